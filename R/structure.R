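# Structure container: a tibble of heavy atoms, one row per atom, ordered by
# residue. Residue indexing is 1-based and contiguous (`res_index`); original
# PDB numbering is kept as metadata (`res_number`, `ins`).

new_structure <- function(atoms, chain_id = "A") {
  need <- c("res_index", "res_name", "res_number", "ins", "atom_name",
            "element", "x", "y", "z", "occupancy", "radius")
  stopifnot(all(need %in% names(atoms)))
  out <- tibble::as_tibble(atoms[need])
  attr(out, "chain_id") <- chain_id
  class(out) <- c("burial_structure", class(tibble::tibble()))
  out
}

#' @export
print.burial_structure <- function(x, ...) {
  cat(sprintf("<burial_structure> chain %s: %d residues, %d atoms\n",
              attr(x, "chain_id") %||% "?", n_residues(x), nrow(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of residues in a structure
#' @param structure A structure tibble from [read_structure()] or
#'   [build_backbone()].
#' @return Integer residue count.
#' @export
n_residues <- function(structure) {
  if (nrow(structure) == 0L) return(0L)
  as.integer(max(structure$res_index))
}

#' Residue types of a structure
#' @inheritParams n_residues
#' @param code `"three"` or `"one"` letter codes.
#' @return Character vector, one entry per residue in order.
#' @export
residue_types <- function(structure, code = c("three", "one")) {
  code <- match.arg(code)
  r3 <- structure$res_name[!duplicated(structure$res_index)]
  if (code == "three") r3 else unname(ifelse(is.na(AA1[r3]), "X", AA1[r3]))
}

#' One-letter sequence of a structure
#' @inheritParams n_residues
#' @return Single string.
#' @export
structure_sequence <- function(structure) {
  paste(residue_types(structure, "one"), collapse = "")
}

# N x 3 coordinate matrix of one named atom per residue; error (naming the
# residue) if absent. For atom "CB", glycine falls back to CA.
atom_coords <- function(structure, atom_name = "CA", gly_fallback = FALSE) {
  n <- n_residues(structure)
  sel <- structure[structure$atom_name == atom_name, ]
  if (gly_fallback) {
    have <- unique(sel$res_index)
    gly <- structure[structure$res_index %in% setdiff(seq_len(n), have) &
                       structure$atom_name == "CA", ]
    sel <- dplyr::bind_rows(sel, gly)
  }
  sel <- sel[!duplicated(sel$res_index), ]
  m <- match(seq_len(n), sel$res_index)
  if (anyNA(m)) {
    abort(sprintf("residue(s) %s lack a %s atom",
                  paste(which(is.na(m)), collapse = ", "), atom_name))
  }
  cbind(sel$x[m], sel$y[m], sel$z[m])
}

#' Cα coordinates of a structure
#' @inheritParams n_residues
#' @return N x 3 numeric matrix.
#' @export
ca_coords <- function(structure) atom_coords(structure, "CA")

#' Read a protein chain from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the first (or requested)
#' chain, strips hydrogens, waters and non-protein hetero groups, maps common
#' modified residues (e.g. MSE) to their parent standard type, resolves
#' alternate locations to the highest-occupancy conformer, and annotates every
#' atom with a radius from the active radii table. Gzipped files are accepted.
#'
#' @param path PDB file (optionally `.gz`).
#' @param chain Chain identifier; default: first chain in the file.
#' @param radii Radii table, see [radii_table()].
#' @return A structure tibble (class `burial_structure`): one row per heavy
#'   atom with columns `res_index` (1-based contiguous), `res_name`,
#'   `res_number`/`ins` (original PDB numbering), `atom_name`, `element`,
#'   `x`, `y`, `z`, `occupancy`, `radius`.
#' @export
read_structure <- function(path, chain = NULL, radii = radii_table()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  real <- path
  if (grepl("\\.gz$", path)) {
    real <- tempfile(fileext = ".pdb")
    writeLines(readLines(path), real)
    on.exit(unlink(real), add = TRUE)
  }
  pdb <- tryCatch(bio3d::read.pdb(real, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) abort(paste0("unparseable PDB: ", conditionMessage(e))))
  at <- tibble::as_tibble(pdb$atom)
  at$chain[is.na(at$chain)] <- " "
  chains <- unique(at$chain)
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    abort(sprintf("chain '%s' not present (found: %s)", chain,
                  paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, ]

  # residue type filtering: standard residues, mapped nonstandard, drop rest
  mapped <- unname(NONSTANDARD_MAP[at$resid])
  at$resid <- unname(ifelse(!is.na(mapped), mapped, at$resid))
  keep <- at$resid %in% AA3
  dropped <- setdiff(unique(at$resid[!keep]), c("HOH", "WAT", "DOD"))
  if (length(dropped)) {
    warn(paste0("dropping non-standard residue type(s): ",
                paste(dropped, collapse = ", ")))
  }
  at <- at[keep, ]
  if (nrow(at) == 0L) abort("no standard protein residues in requested chain")

  # strip hydrogens/deuterium by element symbol (derived from name if absent)
  elem <- toupper(trimws(at$elesy))
  noel <- is.na(elem) | elem == ""
  elem[noel] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[noel])), 1, 1)
  at$element <- elem
  at <- at[!at$element %in% c("H", "D"), ]
  if (nrow(at) == 0L) abort("no heavy atoms in requested chain")

  # altloc: per (residue, atom name) keep the highest-occupancy conformer
  at$o[is.na(at$o)] <- 1
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$.row <- seq_len(nrow(at))
  akey <- paste(at$resno, at$ins, at$elety, sep = "|")
  ord <- order(-at$o, at$alt, method = "radix")
  at <- at[ord, ][!duplicated(akey[ord]), ]
  at <- at[order(at$.row), ]

  # contiguous residue index in file order (insertion codes kept distinct)
  rkey <- paste(at$resno, at$ins, sep = "|")
  at$res_index <- as.integer(match(rkey, unique(rkey)))

  atoms <- tibble::tibble(
    res_index = at$res_index, res_name = at$resid, res_number = at$resno,
    ins = at$ins, atom_name = trimws(at$elety), element = at$element,
    x = at$x, y = at$y, z = at$z, occupancy = at$o,
    radius = assign_radii(at$resid, trimws(at$elety), at$element, radii)
  )
  new_structure(atoms, chain_id = chain)
}

#' Write a structure to a PDB file
#'
#' @inheritParams n_residues
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(structure$x, structure$y, structure$z))),
    resno = structure$res_number,
    resid = structure$res_name,
    eleno = seq_len(nrow(structure)),
    elety = structure$atom_name,
    chain = attr(structure, "chain_id") %||% "A",
    insert = ifelse(structure$ins == "", NA, structure$ins),
    o = structure$occupancy,
    b = rep(0, nrow(structure)),
    elesy = structure$element
  )
  invisible(path)
}

# apply a rigid transform (used by decoy generation and invariance tests)
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- cbind(structure$x, structure$y, structure$z) %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}
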