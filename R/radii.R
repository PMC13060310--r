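# Amino-acid tables and atomic radii.

# the 20 standard residues, three-letter code
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

# common chemically-modified residues mapped to their parent standard type
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                     CSO = "CYS", SEP = "SER", TPO = "THR", PTR = "TYR",
                     MLY = "LYS", M3L = "LYS", KCX = "LYS", CME = "CYS",
                     LLP = "LYS")

# mean residue volumes (A^3); side-chain pseudo-sphere radii are derived from
# the side-chain volume (residue minus glycine) assuming a single sphere
RESIDUE_VOLUME <- c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1,
                    CYS = 108.5, GLN = 143.8, GLU = 138.4, GLY = 60.1,
                    HIS = 153.2, ILE = 166.7, LEU = 166.7, LYS = 168.6,
                    MET = 162.9, PHE = 189.9, PRO = 112.7, SER = 89.0,
                    THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

#' Pseudo side-chain sphere radii
#'
#' Radius (in angstroms) of the single sphere that stands in for each residue
#' type's side chain in the coarse synthetic representation: the sphere whose
#' volume equals the residue's mean volume minus the glycine (backbone-only)
#' volume. Glycine gets no pseudo atom.
#'
#' @return Named numeric vector over the 20 standard three-letter codes
#'   (glycine entry is `NA`).
#' @export
pseudo_sidechain_radii <- function() {
  v <- RESIDUE_VOLUME - RESIDUE_VOLUME[["GLY"]]
  r <- (3 * v / (4 * pi))^(1 / 3)
  r[["GLY"]] <- NA_real_
  r
}

# element-based van der Waals radii (A) used as the fallback when no
# (residue, atom-name) override matches; protein heavy atoms only
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
                   P = 1.80, X = 1.70)

#' Atomic radii table
#'
#' The default radii assignment used by [read_structure()] and the synthetic
#' backbone builder. Atoms are matched first on (residue, atom name), then by
#' element symbol. The shipped defaults are standard van der Waals values
#' (C 1.70, N 1.55, O 1.52, S 1.80 angstroms) plus per-residue pseudo
#' side-chain spheres (atom name `"SCB"`) for the coarse representation; any
#' table with the same columns can be swapped in, e.g. via [read_radii()].
#'
#' @return A tibble with columns `res_name` (`"*"` for any residue),
#'   `atom_name` (`"*"` for any atom), `element`, `radius`.
#' @export
radii_table <- function() {
  psc <- pseudo_sidechain_radii()
  psc <- psc[!is.na(psc)]
  dplyr::bind_rows(
    tibble::tibble(res_name = names(psc), atom_name = "SCB",
                   element = "X", radius = unname(psc)),
    tibble::tibble(res_name = "*", atom_name = "*",
                   element = names(ELEMENT_RADII),
                   radius = unname(ELEMENT_RADII))
  )
}

#' Read a radii table from a key-value config file
#'
#' Plain TSV with columns `res_name`, `atom_name`, `element`, `radius`;
#' rows with `res_name = "*"` and `atom_name = "*"` act as element fallbacks.
#'
#' @param path File path.
#' @return A radii tibble as in [radii_table()].
#' @export
read_radii <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("res_name", "atom_name", "element", "radius")
  if (!all(need %in% names(df))) {
    abort(paste0("radii file must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(df$radius)) || any(df$radius <= 0)) {
    abort("all radii must be finite and positive")
  }
  tibble::as_tibble(df[need])
}

# assign a radius to each atom row given a radii table; errors on atoms that
# match nothing (unknown element with no override)
assign_radii <- function(res_name, atom_name, element, radii) {
  n <- length(res_name)
  out <- rep(NA_real_, n)
  specific <- radii[radii$res_name != "*", , drop = FALSE]
  if (nrow(specific)) {
    key <- paste(res_name, atom_name)
    skey <- paste(specific$res_name, specific$atom_name)
    m <- match(key, skey)
    out[!is.na(m)] <- specific$radius[m[!is.na(m)]]
  }
  fallback <- radii[radii$res_name == "*", , drop = FALSE]
  miss <- is.na(out)
  if (any(miss)) {
    m <- match(element[miss], fallback$element)
    out[miss] <- fallback$radius[m]
  }
  if (anyNA(out)) {
    bad <- unique(element[is.na(out)])
    abort(paste0("no radius for element(s): ", paste(bad, collapse = ", ")))
  }
  out
}
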