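# Agreement scores between native and model encodings: Matthews correlation
# (binary determinant form and its multiclass generalization) and the
# superposition-free Calpha LDDT model-accuracy score.

#' Confusion matrix between native and predicted labels
#'
#' `M[a, b]` counts positions with native label `a` and predicted label `b`.
#'
#' @param native,predicted [label_set()]s (or bare vectors) of equal length;
#'   when both are label sets their kind and alphabet must match.
#' @param alphabet Alphabet to tabulate over; inferred from the label sets or
#'   the sorted union of observed values when omitted.
#' @return A `confusion_matrix`: k x k integer matrix with the alphabet as
#'   dimnames.
#' @export
build_confusion <- function(native, predicted, alphabet = NULL) {
  if (length(native) != length(predicted)) {
    abort("native and predicted labelings differ in length")
  }
  a1 <- attr(native, "alphabet")
  a2 <- attr(predicted, "alphabet")
  if (!is.null(a1) && !is.null(a2) && !identical(a1, a2)) {
    abort("native and predicted label sets have different alphabets")
  }
  k1 <- attr(native, "kind")
  k2 <- attr(predicted, "kind")
  if (!is.null(k1) && !is.null(k2) && !identical(k1, k2)) {
    abort("native and predicted label sets have different kinds")
  }
  if (is.null(alphabet)) alphabet <- a1 %||% a2 %||%
      sort(unique(c(as.character(native), as.character(predicted))))
  m <- table(factor(as.character(native), levels = alphabet),
             factor(as.character(predicted), levels = alphabet))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("native", "predicted")
  class(m) <- c("confusion_matrix", "matrix")
  m
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("native", "predicted", "count")
  tibble::as_tibble(df)
}

new_phi_score <- function(value, degenerate = FALSE) {
  structure(value, degenerate = degenerate, class = "phi_score")
}

#' @export
print.phi_score <- function(x, ...) {
  cat(sprintf("phi = %.6g%s\n", as.numeric(x),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else ""))
  invisible(x)
}

#' Binary Matthews correlation coefficient
#'
#' `phi = det(M) / sqrt(r1 r2 c1 c2)` for a 2x2 confusion matrix M with row
#' sums r and column sums c. When any margin is zero (e.g. a model that
#' predicts no core residues) the coefficient is undefined; it is reported as
#' 0 with a `degenerate` flag, matching the "no correlation" semantics.
#'
#' @param M A 2x2 [build_confusion()] matrix.
#' @return A `phi_score` (numeric in \[-1, 1\] with a `degenerate` attribute).
#' @export
phi_binary <- function(M) {
  M <- unclass(M)
  if (!all(dim(M) == c(2, 2))) abort("phi_binary needs a 2x2 matrix; use phi_multiclass")
  r <- rowSums(M)
  cs <- colSums(M)
  if (any(r == 0) || any(cs == 0)) return(new_phi_score(0, degenerate = TRUE))
  new_phi_score((M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]) / sqrt(prod(r) * prod(cs)))
}

#' Multiclass Matthews correlation coefficient
#'
#' The k-class generalization
#' `phi = (c s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`
#' with `s` the total count, `c = tr(M)`, `p_k` the column sums and `t_k` the
#' row sums. A zero denominator yields a degenerate score of 0. For k = 2 this
#' reduces exactly to [phi_binary()].
#'
#' @param M A k x k (k >= 2) [build_confusion()] matrix.
#' @return A `phi_score`.
#' @export
phi_multiclass <- function(M) {
  M <- unclass(M)
  if (nrow(M) != ncol(M) || nrow(M) < 2) abort("need a square k x k matrix, k >= 2")
  s <- sum(M)
  cc <- sum(diag(M))
  p <- colSums(M)
  t <- rowSums(M)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(new_phi_score(0, degenerate = TRUE))
  new_phi_score((cc * s - sum(p * t)) / den)
}

#' Matthews correlation between two labelings
#'
#' Convenience wrapper: builds the confusion matrix and dispatches to
#' [phi_binary()] or [phi_multiclass()] by alphabet size.
#'
#' @inheritParams build_confusion
#' @return A `phi_score`.
#' @export
phi <- function(native, predicted, alphabet = NULL) {
  M <- build_confusion(native, predicted, alphabet = alphabet)
  if (nrow(M) == 2) phi_binary(M) else phi_multiclass(M)
}

# hot path: binary phi straight from two 0/1 integer vectors (no tables)
phi_pair_fast <- function(a, b) {
  n11 <- sum(a == 1L & b == 1L)
  n00 <- sum(a == 0L & b == 0L)
  n10 <- sum(a == 1L & b == 0L)
  n01 <- sum(a == 0L & b == 1L)
  r1 <- n00 + n01; r2 <- n10 + n11
  c1 <- n00 + n10; c2 <- n01 + n11
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
  (n00 * n11 - n01 * n10) / sqrt(r1) / sqrt(r2) / sqrt(c1) / sqrt(c2)
}

# hot path: multiclass phi from two small-integer-coded vectors
phi_multi_fast <- function(a, b, k) {
  M <- matrix(tabulate((a - 1L) * k + b, nbins = k * k), k, k, byrow = TRUE)
  s <- sum(M)
  cc <- sum(diag(M))
  p <- colSums(M)
  t <- rowSums(M)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(0)
  (cc * s - sum(p * t)) / den
}

#' Calpha local distance difference test (LDDT)
#'
#' Superposition-free model accuracy: the reference set is all Calpha pairs
#' (i, j) of the target with `|i - j| >= min_separation` and target distance
#' strictly below `inclusion_radius`; a pair is preserved at tolerance t iff
#' the model reproduces its distance within t (strict). The per-residue score
#' averages the preserved fraction over the tolerance thresholds; the global
#' score averages residues that have at least one reference pair. LDDT is not
#' symmetric: the first argument is the reference.
#'
#' @param target,model Aligned structures of equal length, Calpha present.
#' @param inclusion_radius Reference-pair inclusion radius in angstroms
#'   (default 15).
#' @param thresholds Distance tolerances in angstroms (default 0.5, 1, 2, 4).
#' @param min_separation Minimum `|i - j|` for reference pairs (default 1,
#'   i.e. exclude only i = j).
#' @return An `lddt_score` list: `global`, `per_residue` (`NA` where a
#'   residue has no reference pairs), and the settings.
#' @export
lddt <- function(target, model, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4), min_separation = 1) {
  ta <- ca_coords(target)
  mo <- ca_coords(model)
  if (nrow(ta) != nrow(mo)) abort("target and model must be aligned to equal length")
  n <- nrow(ta)
  dt <- as.matrix(stats::dist(ta))
  dm <- as.matrix(stats::dist(mo))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  ref <- dt < inclusion_radius & sep >= max(1, min_separation)
  if (!any(ref)) abort("no reference pairs under the inclusion radius")
  dd <- abs(dt - dm)
  frac <- matrix(0, n, length(thresholds))
  npairs <- rowSums(ref)
  for (k in seq_along(thresholds)) {
    frac[, k] <- rowSums(ref & dd < thresholds[k])
  }
  per_res <- ifelse(npairs > 0, rowMeans(frac / pmax(npairs, 1)), NA_real_)
  out <- list(global = mean(per_res, na.rm = TRUE), per_residue = per_res,
              inclusion_radius = inclusion_radius, thresholds = thresholds,
              min_separation = min_separation)
  class(out) <- "lddt_score"
  out
}

#' @export
print.lddt_score <- function(x, ...) {
  cat(sprintf("<lddt_score> global %.4f over %d residues\n",
              x$global, length(x$per_residue)))
  invisible(x)
}

#' @export
tidy.lddt_score <- function(x, ...) {
  tibble::tibble(res_index = seq_along(x$per_residue), lddt = x$per_residue)
}

#' @export
glance.lddt_score <- function(x, ...) {
  tibble::tibble(lddt = x$global, n = length(x$per_residue),
                 inclusion_radius = x$inclusion_radius,
                 n_thresholds = length(x$thresholds))
}
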