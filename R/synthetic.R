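# Self-contained synthetic fixtures: idealized coarse backbones (N, CA, C, O
# plus an optional single typed pseudo-side-chain sphere at the Cbeta
# position), noise-perturbed decoys with a controlled LDDT spread, and full
# benchmark sets so every pipeline stage runs without external data.

# ideal backbone geometry (angstroms / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
unit3 <- function(v) v / sqrt(sum(v^2))

# natural extension reference frame: place D given A-B-C, bond |CD|, angle
# B-C-D and torsion A-B-C-D
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ta <- torsion_deg * pi / 180
  bc <- unit3(C - B)
  nrm <- unit3(cross3(B - A, bc))
  m <- cbind(bc, cross3(nrm, bc), nrm)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  as.numeric(C + m %*% d)
}

# Cbeta from backbone N, CA, C (ideal tetrahedral construction)
cbeta_position <- function(N, CA, C) {
  b <- CA - N
  cc <- C - CA
  a <- cross3(b, cc)
  CA - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

# build a peptide from explicit per-residue (phi, psi); omega fixed at 180
build_peptide <- function(sequence, phi, psi, sidechain_mode = "pseudo",
                          radii = radii_table(), chain_id = "A") {
  n <- length(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  Nc <- Ca <- Cc <- Oc <- matrix(NA_real_, n, 3)
  Nc[1, ] <- c(0, 0, 0)
  Ca[1, ] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  Cc[1, ] <- Ca[1, ] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Cc[i, ] <- place_atom(Cc[i - 1, ], Nc[i, ], Ca[i, ], BOND_CA_C,
                            ANGLE_N_CA_C, phi[i])
    }
    if (i < n) {
      Nc[i + 1, ] <- place_atom(Nc[i, ], Ca[i, ], Cc[i, ], BOND_C_N,
                                ANGLE_CA_C_N, psi[i])
      Ca[i + 1, ] <- place_atom(Ca[i, ], Cc[i, ], Nc[i + 1, ], BOND_N_CA,
                                ANGLE_C_N_CA, 180)
    }
    Oc[i, ] <- place_atom(Nc[i, ], Ca[i, ], Cc[i, ], BOND_C_O,
                          ANGLE_CA_C_O, psi[i] + 180)
  }

  with_sc <- sidechain_mode != "none" & sequence != "GLY"
  sc_name <- if (sidechain_mode == "pseudo") "SCB" else "CB"
  sc_elem <- if (sidechain_mode == "pseudo") "X" else "C"
  bb <- matrix(NA_real_, 4 * n, 3)
  bb[seq(1, 4 * n, 4), ] <- Nc
  bb[seq(2, 4 * n, 4), ] <- Ca
  bb[seq(3, 4 * n, 4), ] <- Cc
  bb[seq(4, 4 * n, 4), ] <- Oc
  sc_idx <- which(with_sc)
  cb <- if (length(sc_idx)) {
    t(vapply(sc_idx, function(i) cbeta_position(Nc[i, ], Ca[i, ], Cc[i, ]),
             numeric(3)))
  } else {
    matrix(numeric(0), 0, 3)
  }
  ri_all <- c(rep(seq_len(n), each = 4), sc_idx)
  xyz <- rbind(bb, cb)
  name_all <- c(rep(c("N", "CA", "C", "O"), n), rep(sc_name, length(sc_idx)))
  elem_all <- c(rep(c("N", "C", "C", "O"), n), rep(sc_elem, length(sc_idx)))
  ord <- order(ri_all, method = "radix")  # stable: backbone before side chain
  atoms <- tibble::tibble(
    res_index = ri_all[ord], res_name = sequence[ri_all[ord]],
    res_number = ri_all[ord], ins = "",
    atom_name = name_all[ord], element = elem_all[ord],
    x = xyz[ord, 1], y = xyz[ord, 2], z = xyz[ord, 3], occupancy = 1
  )
  atoms$radius <- assign_radii(atoms$res_name, atoms$atom_name, atoms$element, radii)
  new_structure(atoms, chain_id = chain_id)
}

# approximate natural amino-acid frequencies for random sequences
AA_FREQ <- c(ALA = .083, ARG = .055, ASN = .040, ASP = .054, CYS = .014,
             GLN = .039, GLU = .067, GLY = .071, HIS = .023, ILE = .059,
             LEU = .097, LYS = .058, MET = .024, PHE = .039, PRO = .047,
             SER = .066, THR = .054, TRP = .011, TYR = .029, VAL = .069)

sample_coil_angles <- function(n) {
  region <- sample.int(3, n, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  phi <- c(-120, -65, 60)[region] + rnorm(n, 0, c(25, 15, 10)[region])
  psi <- c(135, -40, 40)[region] + rnorm(n, 0, c(25, 15, 10)[region])
  cbind(phi, psi)
}

# nonadjacent backbone heavy atoms closer than 2.5 A indicate a self-clash
has_clash <- function(structure) {
  bb <- structure[structure$atom_name %in% c("N", "CA", "C", "O"), ]
  xyz <- cbind(bb$x, bb$y, bb$z)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(bb$res_index, bb$res_index, "-"))
  any(d[sep > 1] < 2.5)
}

# crude hydrophobic collapse: greedy Monte Carlo over coil dihedrals that
# shrinks the hydrophobicity-weighted radius of gyration of the side-chain
# centers (plus a weak all-residue term), rejecting self-clashing moves.
# Gives the coarse targets a packed, preferentially hydrophobic core.
collapse_structure <- function(sequence, phi, psi, coil, sidechain_mode,
                               radii, n_iter = 250) {
  h <- hydro_scale("consensus")[sequence]
  w <- pmax(h, 0) + 0.25
  energy_of <- function(s) {
    cen <- atom_coords(s, if (sidechain_mode == "none") "CA" else
      if (sidechain_mode == "pseudo") "SCB" else "CB", gly_fallback = TRUE)
    mu <- colSums(cen * w) / sum(w)
    sum(w * rowSums(sweep(cen, 2, mu)^2)) / sum(w)
  }
  cur <- build_peptide(sequence, phi, psi, sidechain_mode = sidechain_mode,
                       radii = radii)
  e_cur <- energy_of(cur)
  if (length(coil) == 0L) return(cur)
  for (it in seq_len(n_iter)) {
    i <- coil[sample.int(length(coil), 1)]
    phi2 <- phi; psi2 <- psi
    ang <- sample_coil_angles(1)
    phi2[i] <- ang[1, 1]; psi2[i] <- ang[1, 2]
    cand <- build_peptide(sequence, phi2, psi2, sidechain_mode = sidechain_mode,
                          radii = radii)
    if (has_clash(cand)) next
    e_cand <- energy_of(cand)
    if (e_cand < e_cur) {
      phi <- phi2; psi <- psi2
      cur <- cand; e_cur <- e_cand
    }
  }
  cur
}

#' Build an idealized coarse backbone
#'
#' Places N, Calpha, C and O with ideal bond geometry from segment-wise
#' backbone dihedrals: helices use (phi, psi) = (-57, -47), strands
#' the extended (-135, +135), and coil segments sample the allowed Ramachandran basins
#' (with clash-rejection resampling). `sidechain_mode = "pseudo"` adds one
#' residue-typed pseudo-sphere at the Cbeta position, sized by side-chain
#' volume, so burial varies realistically across residue types.
#'
#' @param segments A data frame (or list of `c(kind, length)`) with columns
#'   `kind` (`"helix"`, `"strand"`, `"coil"`) and `length`.
#' @param sequence Optional three-letter residue types (sampled from natural
#'   frequencies when `NULL`).
#' @param sidechain_mode `"pseudo"`, `"cbeta"` or `"none"`.
#' @param seed Seed (coil sampling and sequence draw).
#' @param radii Radii table.
#' @param max_tries Coil resampling attempts before giving up.
#' @param n_candidates Clash-free candidates to sample; the most compact one
#'   (smallest radius of gyration) seeds the collapse refinement.
#' @param collapse_iter Greedy hydrophobic-collapse Monte Carlo moves over the
#'   coil dihedrals (clash-rejected) applied to the chosen candidate; 0
#'   disables the refinement. Gives globular targets whose buried residues
#'   are preferentially hydrophobic.
#' @return A structure tibble (class `burial_structure`).
#' @export
build_backbone <- function(segments, sequence = NULL, sidechain_mode = "pseudo",
                           seed = 1, radii = radii_table(), max_tries = 200,
                           n_candidates = 25, collapse_iter = 250) {
  if (!is.data.frame(segments)) {
    segments <- tibble::tibble(
      kind = vapply(segments, function(s) as.character(s[[1]]), character(1)),
      length = vapply(segments, function(s) as.integer(s[[2]]), integer(1))
    )
  }
  stopifnot(all(segments$kind %in% c("helix", "strand", "coil")),
            all(segments$length >= 1))
  n <- sum(segments$length)
  if (n < 3) abort("total length must be >= 3")
  kinds <- rep(segments$kind, segments$length)
  with_preserved_rng(seed, {
    reassign_sequence <- is.null(sequence)
    if (is.null(sequence)) {
      sequence <- sample(names(AA_FREQ), n, replace = TRUE, prob = AA_FREQ)
    }
    stopifnot(length(sequence) == n)
    phi <- ifelse(kinds == "helix", -57, -135)
    psi <- ifelse(kinds == "helix", -47, 135)
    coil <- which(kinds == "coil")
    best <- NULL
    best_rg <- Inf
    best_phi <- phi
    best_psi <- psi
    n_ok <- 0L
    for (try in seq_len(max_tries)) {
      if (length(coil)) {
        ang <- sample_coil_angles(length(coil))
        phi[coil] <- ang[, 1]
        psi[coil] <- ang[, 2]
      }
      s <- build_peptide(sequence, phi, psi, sidechain_mode = sidechain_mode,
                         radii = radii)
      if (!has_clash(s)) {
        # among clash-free candidates keep the most compact (smallest radius
        # of gyration), so targets tend toward a genuinely buried core
        ca <- ca_coords(s)
        rg <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
        n_ok <- n_ok + 1L
        if (rg < best_rg) {
          best <- s
          best_rg <- rg
          best_phi <- phi
          best_psi <- psi
        }
        if (length(coil) == 0L || n_ok >= n_candidates) break
      }
      if (length(coil) == 0L) break
    }
    if (is.null(best)) {
      abort("could not build a clash-free backbone (resampling exhausted)")
    }
    if (reassign_sequence && sidechain_mode != "none") {
      # emulate a hydrophobic-inside composition: rank positions by burial
      # depth in the chosen candidate and hand the more hydrophobic types
      # (with noise) to the deeper positions; backbone geometry is unchanged
      cen <- atom_coords(best, if (sidechain_mode == "pseudo") "SCB" else "CB",
                         gly_fallback = TRUE)
      depth <- rowSums(sweep(cen, 2, colMeans(cen))^2)
      h <- hydro_scale("consensus")[sequence]
      sequence[order(depth)] <- sequence[order(h + rnorm(n, 0, 0.8),
                                               decreasing = TRUE)]
      best <- build_peptide(sequence, best_phi, best_psi,
                            sidechain_mode = sidechain_mode, radii = radii)
    }
    if (collapse_iter > 0 && length(coil)) {
      best <- collapse_structure(sequence, best_phi, best_psi, coil,
                                 sidechain_mode, radii, n_iter = collapse_iter)
    }
    best
  })
}

#' Generate scored decoys of a native structure
#'
#' `"gaussian"` mode adds iid 3-D Gaussian noise of the given standard
#' deviation to every atom (covalent geometry is not preserved; no channel in
#' scope depends on it). `"segment_rotate"` rotates one random contiguous
#' residue segment about a random axis through its first Calpha; in that mode
#' the sigma values are rotation-angle standard deviations in degrees. Each
#' decoy's Calpha LDDT against the native is computed and returned.
#'
#' @param native A structure tibble.
#' @param noise_sigmas Noise levels (angstroms, or degrees for
#'   `segment_rotate`).
#' @param n_per_sigma Decoys per noise level.
#' @param perturbation `"gaussian"` or `"segment_rotate"`.
#' @param seed Seed.
#' @return A tibble: `decoy_id`, `sigma`, `structure` (list column), `lddt`.
#' @export
make_decoys <- function(native, noise_sigmas, n_per_sigma = 1,
                        perturbation = c("gaussian", "segment_rotate"),
                        seed = 1) {
  perturbation <- match.arg(perturbation)
  stopifnot(all(noise_sigmas >= 0), n_per_sigma >= 1)
  n <- n_residues(native)
  with_preserved_rng(seed, {
    # sigma cycles fastest so any truncated prefix still spans the ladder
    grid <- expand.grid(sigma = noise_sigmas, rep = seq_len(n_per_sigma))
    out <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
      sig <- grid$sigma[g]
      dec <- native
      if (perturbation == "gaussian") {
        dec$x <- dec$x + rnorm(nrow(dec), 0, sig)
        dec$y <- dec$y + rnorm(nrow(dec), 0, sig)
        dec$z <- dec$z + rnorm(nrow(dec), 0, sig)
      } else {
        len <- max(2L, min(n - 1L, as.integer(round(n / 4))))
        start <- sample.int(n - len + 1L, 1)
        segres <- seq(start, start + len - 1L)
        angle <- rnorm(1, 0, sig) * pi / 180
        axis <- unit3(rnorm(3))
        ca0 <- ca_coords(native)[start, ]
        K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                      axis[2], -axis[1], 0), 3, 3)
        R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
        sel <- dec$res_index %in% segres
        xyz <- sweep(cbind(dec$x, dec$y, dec$z)[sel, , drop = FALSE], 2, ca0)
        xyz <- xyz %*% t(R)
        dec$x[sel] <- xyz[, 1] + ca0[1]
        dec$y[sel] <- xyz[, 2] + ca0[2]
        dec$z[sel] <- xyz[, 3] + ca0[3]
      }
      tibble::tibble(decoy_id = sprintf("d%03d", g), sigma = sig,
                     structure = list(dec),
                     lddt = lddt(native, dec)$global)
    })
    out
  })
}

# default noise ladder giving decoy LDDT values spanning roughly [0.25, 1]
DEFAULT_DECOY_SIGMAS <- c(0.1, 0.2, 0.3, 0.45, 0.6, 0.8, 1.1, 1.5, 2.2, 3.5)

# random mixed topology: short coils linking helices and strands
random_segments <- function(target_length) {
  kinds <- "coil"
  lens <- sample(2:4, 1)
  while (sum(lens) < target_length - 4) {
    kind <- sample(c("helix", "strand"), 1)
    klen <- if (kind == "helix") sample(8:14, 1) else sample(5:8, 1)
    kinds <- c(kinds, kind, "coil")
    lens <- c(lens, klen, sample(2:5, 1))
  }
  tibble::tibble(kind = kinds, length = as.integer(lens))
}

#' Build a complete synthetic benchmark
#'
#' Generates mixed-topology targets and noise-perturbed decoys spanning a wide
#' LDDT range, and precomputes every label channel (burial, contacts,
#' secondary structure, hydrogen-bond satisfaction) plus per-decoy rSASA, so
#' the information-efficiency and robustness analyses can run directly.
#'
#' @param n_targets Number of targets.
#' @param n_decoys Decoys per target.
#' @param sigmas Gaussian noise ladder in angstroms.
#' @param target_length_range Min/max residue count per target.
#' @param seed Master seed (targets, decoys and coil sampling draw from
#'   derived substreams).
#' @param cutoff rSASA burial cutoff.
#' @param probe,n_points SASA settings.
#' @param contact_cutoff,contact_min_separation Contact channel settings.
#' @param min_core_fraction Minimal buried fraction a generated target must
#'   reach (topologies are resampled until it does); emulates the globular
#'   single domains real benchmarks consist of.
#' @param radii Radii table.
#' @return A `burial_benchmark` list: per target its structure, residue
#'   types, native rSASA and channels, and a decoys tibble with `lddt`,
#'   `rsasa` and per-channel label list columns.
#' @export
make_benchmark <- function(n_targets = 3, n_decoys = 40,
                           sigmas = DEFAULT_DECOY_SIGMAS,
                           target_length_range = c(50, 70), seed = 1,
                           cutoff = 0.1, probe = 1.4, n_points = 960,
                           contact_cutoff = 8, contact_min_separation = 0,
                           min_core_fraction = 0.08, radii = radii_table()) {
  stopifnot(n_targets >= 1, n_decoys >= 1)
  refs <- reference_areas(radii = radii, probe = probe, n_points = n_points,
                          sidechain_mode = "pseudo")
  n_per_sigma <- max(1L, ceiling(n_decoys / length(sigmas)))

  channels_of <- function(s, rs = NULL) {
    if (is.null(rs)) {
      rs <- rsasa(s, shrake_rupley(s, probe = probe, n_points = n_points), refs)$rsasa
    }
    hb <- hbond_satisfaction(s)
    list(
      rsasa = rs,
      burial = core_labels(rs, cutoff = cutoff),
      contacts = as.integer(as.character(flatten_pairs(
        contact_map(s, cutoff = contact_cutoff,
                    min_separation = contact_min_separation)))),
      ss = as.character(secondary_structure(s, hb)),
      hbond = hb$satisfied
    )
  }

  target_rsasa <- function(s) {
    rsasa(s, shrake_rupley(s, probe = probe, n_points = n_points), refs)$rsasa
  }
  targets <- lapply(seq_len(n_targets), function(ti) {
    t_seed <- (seed + 7001 * ti) %% 2147483647
    native <- NULL
    nat_rs <- NULL
    best_fc <- -1
    # retry topologies until the fold is globular enough to have a buried
    # core (benchmark targets emulate single compact domains); keep the most
    # buried attempt if none reaches the floor
    for (attempt in 0:11) {
      a_seed <- (t_seed + 100003 * attempt) %% 2147483647
      segs <- with_preserved_rng(a_seed, {
        L <- sample(seq(target_length_range[1], target_length_range[2]), 1)
        random_segments(L)
      })
      cand <- tryCatch(
        build_backbone(segs, seed = a_seed + 1, radii = radii),
        error = function(e) NULL)
      if (is.null(cand)) next
      rs <- target_rsasa(cand)
      fc <- mean(core_labels(rs, cutoff = cutoff))
      if (fc > best_fc) {
        native <- cand
        nat_rs <- rs
        best_fc <- fc
      }
      if (best_fc >= min_core_fraction) break
    }
    if (is.null(native)) abort("failed to generate a clash-free target")
    dec <- make_decoys(native, sigmas, n_per_sigma = n_per_sigma,
                       seed = t_seed + 2)
    dec <- dec[seq_len(min(n_decoys, nrow(dec))), ]
    nat_ch <- channels_of(native, rs = nat_rs)
    dch <- lapply(dec$structure, channels_of)
    dec$rsasa <- lapply(dch, `[[`, "rsasa")
    dec$burial <- lapply(dch, `[[`, "burial")
    dec$contacts <- lapply(dch, `[[`, "contacts")
    dec$ss <- lapply(dch, `[[`, "ss")
    dec$hbond <- lapply(dch, `[[`, "hbond")
    list(name = sprintf("t%02d", ti), structure = native,
         n = n_residues(native), res_types = residue_types(native),
         rsasa = nat_ch$rsasa,
         native = nat_ch[c("burial", "contacts", "ss", "hbond")],
         decoys = dec)
  })
  out <- list(targets = targets,
              config = list(seed = seed, cutoff = cutoff, probe = probe,
                            n_points = n_points, sigmas = sigmas,
                            contact_cutoff = contact_cutoff,
                            contact_min_separation = contact_min_separation))
  class(out) <- "burial_benchmark"
  out
}

#' @export
print.burial_benchmark <- function(x, ...) {
  nd <- sum(vapply(x$targets, function(t) nrow(t$decoys), integer(1)))
  cat(sprintf("<burial_benchmark> %d targets, %d scored decoys\n",
              length(x$targets), nd))
  invisible(x)
}

#' @export
glance.burial_benchmark <- function(x, ...) {
  ld <- unlist(lapply(x$targets, function(t) t$decoys$lddt))
  tibble::tibble(
    n_targets = length(x$targets),
    n_decoys = length(ld),
    n_residues = sum(vapply(x$targets, `[[`, numeric(1), "n")),
    lddt_min = min(ld), lddt_max = max(ld),
    lddt_bins_occupied = length(unique(pmin(pmax(floor(ld * 20) + 1, 1), 20)))
  )
}

# channel alphabets used across the package
CHANNEL_ALPHABETS <- list(burial = c("0", "1"), contacts = c("0", "1"),
                          ss = c("H", "E", "C"), hbond = c("0", "1"))

# fetch the stored labels of a channel for a target (native or a decoy row)
channel_labels <- function(target, channel, native = TRUE, decoy = NULL) {
  if (native) {
    target$native[[channel]]
  } else {
    target$decoys[[channel]][[decoy]]
  }
}

#' Information model fitted on a benchmark's native labels
#'
#' @param benchmark A [make_benchmark()] object.
#' @param channel Channel name.
#' @return An [fit_information()] model.
#' @export
benchmark_information <- function(benchmark, channel) {
  alpha <- CHANNEL_ALPHABETS[[channel]]
  if (is.null(alpha)) abort(paste0("unknown channel: ", channel))
  corpus <- lapply(benchmark$targets, function(t) {
    as.character(channel_labels(t, channel, native = TRUE))
  })
  fit_information(corpus, alphabet = alpha)
}

#' Write a benchmark to disk
#'
#' Writes target and decoy structures as PDB files, per-target channel caches
#' as TSV, and a JSON manifest tying them together (paths, LDDT, settings).
#'
#' @param benchmark A [make_benchmark()] object.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pack <- function(v) paste(v, collapse = "")
  manifest <- list(config = benchmark$config, targets = list())
  for (t in benchmark$targets) {
    tdir <- file.path(dir, t$name)
    dir.create(tdir, showWarnings = FALSE)
    write_structure(t$structure, file.path(tdir, "native.pdb"))
    dtab <- tibble::tibble(
      decoy_id = t$decoys$decoy_id, sigma = t$decoys$sigma,
      lddt = t$decoys$lddt,
      burial = vapply(t$decoys$burial, pack, character(1)),
      contacts = vapply(t$decoys$contacts, pack, character(1)),
      ss = vapply(t$decoys$ss, pack, character(1)),
      hbond = vapply(t$decoys$hbond, pack, character(1)),
      rsasa = vapply(t$decoys$rsasa, function(v) paste(signif(v, 6), collapse = ","),
                     character(1))
    )
    utils::write.table(dtab, file.path(tdir, "decoys.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (d in seq_len(nrow(t$decoys))) {
      write_structure(t$decoys$structure[[d]],
                      file.path(tdir, paste0(t$decoys$decoy_id[d], ".pdb")))
    }
    manifest$targets[[t$name]] <- list(
      name = t$name, n = t$n, res_types = t$res_types,
      native_pdb = file.path(t$name, "native.pdb"),
      decoys_tsv = file.path(t$name, "decoys.tsv"),
      rsasa = signif(t$rsasa, 6),
      native_burial = pack(t$native$burial),
      native_contacts = pack(t$native$contacts),
      native_ss = pack(t$native$ss),
      native_hbond = pack(t$native$hbond)
    )
  }
  path <- file.path(dir, "bench.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a benchmark manifest written by [write_benchmark()]
#'
#' Decoy structures are not reloaded (label channels, rSASA and LDDT are
#' cached in the manifest); target structures are parsed from their PDBs.
#'
#' @param path The `bench.json` manifest path.
#' @return A `burial_benchmark` object.
#' @export
read_benchmark <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  unpack_int <- function(s) as.integer(strsplit(s, "")[[1]])
  unpack_chr <- function(s) strsplit(s, "")[[1]]
  tl <- man$targets
  targets <- lapply(names(tl), function(nm) {
    t <- tl[[nm]]
    dtab <- tibble::as_tibble(utils::read.delim(
      file.path(dir, t$decoys_tsv), stringsAsFactors = FALSE,
      colClasses = c(decoy_id = "character", burial = "character",
                     contacts = "character", ss = "character",
                     hbond = "character", rsasa = "character")))
    dec <- tibble::tibble(
      decoy_id = dtab$decoy_id, sigma = dtab$sigma, lddt = dtab$lddt,
      structure = vector("list", nrow(dtab)),
      rsasa = lapply(strsplit(dtab$rsasa, ","), as.numeric),
      burial = lapply(dtab$burial, unpack_int),
      contacts = lapply(dtab$contacts, unpack_int),
      ss = lapply(dtab$ss, unpack_chr),
      hbond = lapply(dtab$hbond, unpack_int)
    )
    list(name = t$name, structure = read_structure(file.path(dir, t$native_pdb)),
         n = t$n, res_types = t$res_types, rsasa = as.numeric(t$rsasa),
         native = list(burial = unpack_int(t$native_burial),
                       contacts = unpack_int(t$native_contacts),
                       ss = unpack_chr(t$native_ss),
                       hbond = unpack_int(t$native_hbond)),
         decoys = dec)
  })
  out <- list(targets = targets, config = man$config)
  class(out) <- "burial_benchmark"
  out
}
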