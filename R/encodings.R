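# Label channels: binary contact maps over residue pairs, backbone
# hydrogen-bond satisfaction via the Kabsch-Sander electrostatic criterion,
# a simplified 3-state secondary-structure assignment, and ingestion of
# external per-residue alphabet strings (e.g. 3Di, predicted burial).

#' Construct a label set
#'
#' Uniform container for per-residue or per-pair categorical labels over a
#' finite alphabet.
#'
#' @param labels Character (or coercible) vector of labels.
#' @param alphabet Ordered character vector of allowed labels.
#' @param kind `"residue"` or `"pair"`.
#' @return A `label_set`: character vector with `alphabet` and `kind`
#'   attributes.
#' @export
label_set <- function(labels, alphabet, kind = c("residue", "pair")) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  alphabet <- as.character(alphabet)
  bad <- which(!labels %in% alphabet)
  if (length(bad)) {
    abort(sprintf("label '%s' at position %d is not in the alphabet",
                  labels[bad[1]], bad[1]))
  }
  structure(labels, alphabet = alphabet, kind = kind, class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %s kind, %d labels over alphabet {%s}\n",
              attr(x, "kind"), length(x),
              paste(attr(x, "alphabet"), collapse = ",")))
  invisible(x)
}

#' Parse an external per-residue label string
#'
#' Ingests alphabet strings produced by external encoders (a 20-letter 3Di
#' string, a 0/1 predicted-burial string, ...). Accepts a bare string or a
#' FASTA-like single-record file content.
#'
#' @param text Single string of labels, one character per residue.
#' @param alphabet Ordered character vector of allowed single-character
#'   labels.
#' @param n Optional expected length (e.g. the trimmed structure length).
#' @return A residue-kind [label_set()].
#' @export
ingest_labels <- function(text, alphabet, n = NULL) {
  if (length(text) > 1 || grepl("^>", text)) {
    lines <- if (length(text) > 1) text else strsplit(text, "\n")[[1]]
    text <- paste(lines[!grepl("^>", lines)], collapse = "")
  }
  chars <- strsplit(trimws(text), "")[[1]]
  if (!is.null(n) && length(chars) != n) {
    abort(sprintf("label string has %d characters but %d residues expected",
                  length(chars), n))
  }
  label_set(chars, alphabet = alphabet, kind = "residue")
}

#' Binary residue-pair contact map
#'
#' `c_ij = 1` iff the chosen atoms of residues i and j are strictly closer
#' than `cutoff` and `|i - j| > min_separation`. The default (Calpha atoms,
#' 8 angstroms, no separation filter) scores all N(N-1)/2 pairs; the
#' `"esm2"` preset uses Cbeta atoms (Calpha for glycine), 8 angstroms and
#' `min_separation = 6`.
#'
#' @inheritParams n_residues
#' @param cutoff Distance cutoff in angstroms (default 8).
#' @param atom_mode `"ca"` or `"cb"` (glycine falls back to Calpha).
#' @param min_separation Pairs with `|i - j| <= min_separation` are excluded.
#' @param preset Optional named configuration; `"esm2"` sets
#'   `atom_mode = "cb"`, `min_separation = 6`.
#' @return A `contact_map` list: symmetric 0/1 integer `mat` (diagonal and
#'   excluded separations `NA`), plus the settings.
#' @export
contact_map <- function(structure, cutoff = 8, atom_mode = c("ca", "cb"),
                        min_separation = 0, preset = NULL) {
  if (!is.null(preset)) {
    if (preset == "esm2") {
      atom_mode <- "cb"
      min_separation <- 6
    } else abort(paste0("unknown preset: ", preset))
  }
  atom_mode <- match.arg(atom_mode)
  xyz <- if (atom_mode == "ca") {
    atom_coords(structure, "CA")
  } else {
    atom_coords(structure, "CB", gly_fallback = TRUE)
  }
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  mat <- matrix(NA_integer_, n, n)
  ok <- sep > min_separation
  mat[ok] <- as.integer(d[ok] < cutoff)
  out <- list(mat = mat, cutoff = cutoff, atom_mode = atom_mode,
              min_separation = min_separation, n = n)
  class(out) <- "contact_map"
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> N=%d, %s atoms, cutoff %.1f A, min separation %d, %d contacts\n",
              x$n, toupper(x$atom_mode), x$cutoff, x$min_separation,
              sum(x$mat[upper.tri(x$mat)], na.rm = TRUE)))
  invisible(x)
}

# row-major upper-triangle pair order (i < j), minus excluded separations;
# the single canonical order used by every pair-label consumer
pair_indices <- function(n, min_separation = 0) {
  if (n < 2) return(tibble::tibble(i = integer(), j = integer()))
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  keep <- (j - i) > min_separation
  tibble::tibble(i = i[keep], j = j[keep])
}

#' Flatten a contact map to a pair label set
#'
#' Fixed row-major upper-triangle traversal (`(1,2), (1,3), ..., (2,3), ...`)
#' skipping excluded separations.
#'
#' @param map A [contact_map()].
#' @return A pair-kind [label_set()] over alphabet `c("0", "1")`.
#' @export
flatten_pairs <- function(map) {
  idx <- pair_indices(map$n, map$min_separation)
  label_set(as.character(map$mat[cbind(idx$i, idx$j)]),
            alphabet = c("0", "1"), kind = "pair")
}

#' Rebuild a contact map matrix from flattened pair labels
#'
#' @param labels Pair-kind labels (from [flatten_pairs()]).
#' @param n Residue count.
#' @param min_separation Separation filter used when flattening.
#' @return Symmetric 0/1 integer matrix with `NA` on excluded entries.
#' @export
unflatten_pairs <- function(labels, n, min_separation = 0) {
  idx <- pair_indices(n, min_separation)
  if (nrow(idx) != length(labels)) abort("label length does not match n")
  mat <- matrix(NA_integer_, n, n)
  mat[cbind(idx$i, idx$j)] <- as.integer(as.character(labels))
  mat[cbind(idx$j, idx$i)] <- mat[cbind(idx$i, idx$j)]
  mat
}

# ---- backbone hydrogen bonds (Kabsch-Sander) --------------------------------

# Kabsch-Sander electrostatic energy (kcal/mol) between donor N-H (i) and
# acceptor C=O (j): E = q1*q2*(1/rON + 1/rCH - 1/rOH - 1/rCN)*f
ks_energy <- function(N, H, C, O) {
  q1q2f <- 0.42 * 0.20 * 332
  d <- function(a, b) sqrt(sum((a - b)^2))
  q1q2f * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

#' Backbone hydrogen-bond assignment and satisfaction
#'
#' Scores every candidate backbone N-H(i) to C=O(j) bond with the
#' Kabsch-Sander electrostatic energy and assigns a bond when the energy falls
#' below the cutoff. Amide hydrogens are reconstructed geometrically (1.01
#' angstroms from N, opposite the bisector of the C(i-1)-N and Calpha-N
#' directions); prolines and the N-terminal residue have no donor. A residue
#' is "satisfied" when its backbone participates in at least one assigned
#' bond, as donor or acceptor.
#'
#' @inheritParams n_residues
#' @param energy_cutoff Bond assignment threshold in kcal/mol (default -0.5).
#' @return An `hbond_assignment` list: `bonds` tibble (`donor`, `acceptor`,
#'   `energy`), integer `satisfied` vector, and the cutoff.
#' @export
hbond_satisfaction <- function(structure, energy_cutoff = -0.5) {
  n <- n_residues(structure)
  Nc <- atom_coords(structure, "N")
  Ca <- atom_coords(structure, "CA")
  Cc <- atom_coords(structure, "C")
  Oc <- atom_coords(structure, "O")
  types <- residue_types(structure)

  unit <- function(v) v / sqrt(sum(v^2))
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (types[i] == "PRO") next
    H[i, ] <- Nc[i, ] + 1.01 * unit(unit(Nc[i, ] - Cc[i - 1, ]) +
                                      unit(Nc[i, ] - Ca[i, ]))
  }

  bonds <- list()
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      # cheap prefilter: Calpha pairs beyond 9 A cannot form a backbone bond
      if (sum((Ca[j, ] - Ca[i, ])^2) > 81) next
      e <- ks_energy(Nc[i, ], H[i, ], Cc[j, ], Oc[j, ])
      if (e < energy_cutoff) {
        bonds[[length(bonds) + 1]] <- c(donor = i, acceptor = j, energy = e)
      }
    }
  }
  bonds <- if (length(bonds)) {
    tibble::as_tibble(do.call(rbind, bonds))
  } else {
    tibble::tibble(donor = integer(), acceptor = integer(), energy = numeric())
  }
  satisfied <- as.integer(seq_len(n) %in% c(bonds$donor, bonds$acceptor))
  out <- list(bonds = bonds, satisfied = satisfied,
              energy_cutoff = energy_cutoff, n = n)
  class(out) <- "hbond_assignment"
  out
}

#' @export
print.hbond_assignment <- function(x, ...) {
  cat(sprintf("<hbond_assignment> %d residues, %d bonds, %d satisfied (cutoff %.2f kcal/mol)\n",
              x$n, nrow(x$bonds), sum(x$satisfied), x$energy_cutoff))
  invisible(x)
}

#' Simplified 3-state secondary structure
#'
#' Assigns H/E/C from the hydrogen-bond pattern: a run of at least two
#' consecutive O(i)..H-N(i+4) bonds marks residues i+1..i+4 as helix; parallel
#' or antiparallel bridge patterns between non-local bonded pairs mark both
#' partners as strand; everything else is coil. This is a deliberately
#' simplified Kabsch-Sander-style detector, not a DSSP replacement.
#'
#' @inheritParams n_residues
#' @param hbonds An [hbond_satisfaction()] result for `structure` (computed
#'   when `NULL`).
#' @return A residue-kind [label_set()] over alphabet `c("H", "E", "C")`.
#' @export
secondary_structure <- function(structure, hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- hbond_satisfaction(structure)
  n <- hbonds$n
  lab <- rep("C", n)
  hb <- matrix(FALSE, n, n)
  if (nrow(hbonds$bonds)) hb[cbind(hbonds$bonds$acceptor, hbonds$bonds$donor)] <- TRUE

  # turn(i): O(i) accepts from N-H(i+4)
  turn4 <- vapply(seq_len(n), function(i) i + 4 <= n && hb[i, i + 4], logical(1))
  for (i in seq_len(n - 1)) {
    if (turn4[i] && turn4[i + 1]) lab[(i + 1):min(i + 4, n)] <- "H"
  }

  # bridges between residues i < j separated by > 2: antiparallel when
  # O(i)<-N(j) and O(j)<-N(i); parallel when O(i-1)<-N(j) and O(j)<-N(i+1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i <= 2) next
      anti <- hb[i, j] && hb[j, i]
      par <- i > 1 && j < n && hb[i - 1, j] && hb[j, i + 1]
      if (anti || par) {
        if (lab[i] == "C") lab[i] <- "E"
        if (lab[j] == "C") lab[j] <- "E"
      }
    }
  }
  label_set(lab, alphabet = c("H", "E", "C"), kind = "residue")
}
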