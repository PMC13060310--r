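# Shrake-Rupley solvent accessible surface area, rSASA normalization against
# a self-consistent extended Gly-X-Gly reference state, and binary core
# labels (buried iff rSASA < cutoff, default 0.1).

# deterministic golden-section spiral points on the unit sphere; no RNG so
# SASA is bit-reproducible for fixed settings
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA by the Shrake-Rupley test-point method: each atom's sphere is
#' expanded by the probe radius and sampled with a deterministic golden-section
#' spiral of `n_points` points; a point is accessible iff it lies outside every
#' other expanded sphere. Hydrogens are already stripped at parse time, so only
#' heavy atoms contribute.
#'
#' @inheritParams n_residues
#' @param probe Probe radius in angstroms (default 1.4, a water molecule).
#' @param n_points Test points per atom (default 960; must be >= 32).
#' @return A `sasa_result` list: `per_atom` and `per_residue` areas in
#'   square angstroms, plus the settings used.
#' @export
shrake_rupley <- function(structure, probe = 1.4, n_points = 960) {
  if (n_points < 32) abort("n_points must be >= 32")
  if (any(!is.finite(structure$radius)) || any(structure$radius <= 0)) {
    abort("all atoms must carry a positive radius")
  }
  xyz <- cbind(structure$x, structure$y, structure$z)
  n <- nrow(xyz)
  R <- structure$radius + probe
  pts <- golden_spiral_points(n_points)

  # neighbour lists from the pairwise distance matrix (structures here are
  # small; hundreds to a few thousand atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    p <- pts * R[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      cnb <- xyz[nb, , drop = FALSE]
      D2 <- outer(rowSums(p^2), rep(1, length(nb))) -
        2 * p %*% t(cnb) +
        outer(rep(1, n_points), rowSums(cnb^2))
      inside <- D2 < outer(rep(1, n_points), R[nb]^2)
      acc <- sum(rowSums(inside) == 0L)
    }
    per_atom[i] <- 4 * pi * R[i]^2 * acc / n_points
  }
  per_residue <- as.numeric(tapply(per_atom, structure$res_index, sum))
  out <- list(per_atom = per_atom, per_residue = per_residue,
              probe = probe, n_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, %d residues, total %.1f A^2 (probe %.2f A, %d points)\n",
              length(x$per_atom), length(x$per_residue), sum(x$per_atom),
              x$probe, x$n_points))
  invisible(x)
}

# cache of reference tables keyed by settings so changing probe/points/radii
# always recomputes
.ref_cache <- new.env(parent = emptyenv())

#' Reference accessible areas per residue type
#'
#' The rSASA denominator: for each residue type X, the SASA of X as the
#' central residue of an extended Gly-X-Gly tripeptide, computed with the same
#' radii, probe, point count and side-chain representation as production runs
#' (self-consistent reference state). Results are cached per settings.
#'
#' @param radii Radii table.
#' @inheritParams shrake_rupley
#' @param sidechain_mode Side-chain representation of the host tripeptide;
#'   must match the structures being normalized (`"pseudo"`, `"cbeta"` or
#'   `"none"`).
#' @return Named numeric vector: maximum accessible area (square angstroms)
#'   per three-letter residue code.
#' @export
reference_areas <- function(radii = radii_table(), probe = 1.4,
                            n_points = 960, sidechain_mode = "pseudo") {
  key <- paste(probe, n_points, sidechain_mode,
               paste(round(radii$radius, 6), collapse = ","),
               paste(radii$res_name, radii$atom_name, collapse = ","), sep = "#")
  hit <- get0(key, envir = .ref_cache)
  if (!is.null(hit)) return(hit)
  out <- vapply(AA3, function(aa) {
    tri <- tryCatch(
      build_peptide(c("GLY", aa, "GLY"), phi = rep(-135, 3), psi = rep(135, 3),
                    sidechain_mode = sidechain_mode, radii = radii),
      error = function(e) abort(sprintf("reference build failed for %s: %s",
                                        aa, conditionMessage(e))))
    shrake_rupley(tri, probe = probe, n_points = n_points)$per_residue[2]
  }, numeric(1))
  assign(key, out, envir = .ref_cache)
  out
}

#' Relative solvent accessibility per residue
#'
#' Fraction of each residue's surface that is exposed: residue SASA divided by
#' the reference area for its type, clamped to `[0, clamp_max]`. Values above
#' 1 are legal (a conformation can expose slightly more area than the extended
#' reference) and are never core.
#'
#' @inheritParams n_residues
#' @param sasa A [shrake_rupley()] result for `structure`.
#' @param refs Named reference areas, see [reference_areas()].
#' @param clamp_max Upper clamp for the ratio (default 1.5).
#' @return A tibble with `res_index`, `res_name`, `rsasa`.
#' @export
rsasa <- function(structure, sasa, refs, clamp_max = 1.5) {
  types <- residue_types(structure)
  miss <- setdiff(unique(types), names(refs))
  if (length(miss)) {
    abort(paste0("no reference area for residue type(s): ",
                 paste(miss, collapse = ", ")))
  }
  v <- pmin(pmax(sasa$per_residue / unname(refs[types]), 0), clamp_max)
  tibble::tibble(res_index = seq_along(v), res_name = types, rsasa = v)
}

#' Binary core-identity labels from rSASA
#'
#' A residue is core (`b_i = 1`) iff its rSASA is strictly below the cutoff
#' (default 0.1), and surface (`b_i = 0`) otherwise.
#'
#' @param rsasa A tibble from [rsasa()] or a bare numeric vector of rSASA
#'   values.
#' @param cutoff Burial cutoff in (0, 1], default 0.1.
#' @return If given a tibble, the tibble with a `core` integer column added;
#'   if given a numeric vector, an integer 0/1 vector.
#' @export
core_labels <- function(rsasa, cutoff = 0.1) {
  if (!(cutoff > 0 && cutoff <= 1)) abort("cutoff must be in (0, 1]")
  if (is.data.frame(rsasa)) {
    rsasa$core <- as.integer(rsasa$rsasa < cutoff)
    return(rsasa)
  }
  as.integer(rsasa < cutoff)
}

#' Per-residue burial encoding of a structure
#'
#' One-shot pipeline: Shrake-Rupley SASA, rSASA normalization against the
#' self-consistent reference state, and binary core labels.
#'
#' @inheritParams shrake_rupley
#' @inheritParams core_labels
#' @param radii Radii table.
#' @param refs Reference areas; computed from `radii`/`probe`/`n_points` when
#'   `NULL`.
#' @param sidechain_mode Reference-state side-chain representation (used only
#'   when `refs` is `NULL`).
#' @return A tibble with `res_index`, `res_name`, `rsasa`, `core`.
#' @export
encode_burial <- function(structure, cutoff = 0.1, probe = 1.4, n_points = 960,
                          radii = radii_table(), refs = NULL,
                          sidechain_mode = "pseudo") {
  if (is.null(refs)) {
    refs <- reference_areas(radii = radii, probe = probe, n_points = n_points,
                            sidechain_mode = sidechain_mode)
  }
  s <- shrake_rupley(structure, probe = probe, n_points = n_points)
  core_labels(rsasa(structure, s, refs), cutoff = cutoff)
}

#' Sensitivity of the burial channel to the rSASA cutoff
#'
#' For each candidate cutoff, relabels every native and decoy burial vector in
#' the benchmark from its stored rSASA values, scores each decoy with the
#' Matthews correlation of native-vs-decoy labels, and reports the flattened
#' bootstrap Spearman correlation with LDDT together with the fraction of
#' native residues labeled core.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param cutoffs Numeric vector of rSASA cutoffs in (0, 1].
#' @param seed Seed for the bootstrap resampling.
#' @param ... Passed to [flattened_spearman()].
#' @return A tibble with `cutoff`, `rho`, `f_core`.
#' @export
cutoff_scan <- function(benchmark, cutoffs, seed = 1, ...) {
  lddt_all <- unlist(lapply(benchmark$targets, function(t) t$decoys$lddt))
  if (length(lddt_all) < 2 || length(unique(lddt_all)) < 2) {
    abort("benchmark is degenerate: need >= 2 decoys with distinct LDDT")
  }
  purrr::map_dfr(cutoffs, function(cut) {
    phis <- unlist(lapply(benchmark$targets, function(t) {
      bn <- core_labels(t$rsasa, cutoff = cut)
      vapply(t$decoys$rsasa, function(rv) {
        phi_pair_fast(bn, core_labels(rv, cutoff = cut))
      }, numeric(1))
    }))
    nat <- unlist(lapply(benchmark$targets, function(t) core_labels(t$rsasa, cut)))
    tibble::tibble(
      cutoff = cut,
      rho = as.numeric(flattened_spearman(phis, lddt_all, seed = seed, ...)),
      f_core = mean(nat)
    )
  })
}
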