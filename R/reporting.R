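# Summary artifacts: per-channel information-efficiency tables, robustness
# tables and core-hydrophobicity-by-LDDT-bin tables.

#' Summarize channels by information efficiency
#'
#' One row per channel: the full-information correlation and bits per
#' residue (the curve point at the largest sampled fraction) and the I*
#' needed to reach the correlation threshold, sorted by I* ascending with
#' channels that never reach the threshold last.
#'
#' @param curves Named list of [rho_vs_I_curve()] tibbles.
#' @param threshold Correlation threshold for I* (default 0.9).
#' @return A tibble: `channel`, `rho_full`, `i_full`, `i_star`, `n_labels`.
#' @export
summarize_channels <- function(curves, threshold = 0.9) {
  if (length(curves) == 0) abort("need at least one channel curve")
  if (is.null(names(curves))) {
    names(curves) <- vapply(curves, function(cv) {
      attr(cv, "channel") %||% "channel"
    }, character(1))
  }
  out <- purrr::map_dfr(names(curves), function(nm) {
    cv <- curves[[nm]]
    full <- cv[which.max(cv$fraction), ]
    tibble::tibble(channel = nm, rho_full = full$rho, i_full = full$i_bits,
                   i_star = i_star(cv, rho_threshold = threshold),
                   n_labels = if ("n_r" %in% names(cv)) full$n_r else NA_integer_)
  })
  out[order(is.na(out$i_star), out$i_star), ]
}

#' Core-hydrophobicity differences for every decoy in a benchmark
#'
#' Computes `deltaH = H_native - H_decoy` per decoy from the stored burial
#' labels, paired with the decoy's LDDT.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param scale Hydrophobicity scale, see [hydro_scale()].
#' @return A tibble: `target`, `decoy`, `lddt`, `delta_h`.
#' @export
delta_h_table <- function(benchmark, scale = hydro_scale()) {
  purrr::map_dfr(benchmark$targets, function(t) {
    hn <- core_hydrophobicity(t$native$burial, t$res_types, scale)
    tibble::tibble(
      target = t$name, decoy = t$decoys$decoy_id, lddt = t$decoys$lddt,
      delta_h = vapply(t$decoys$burial, function(bp) {
        delta_hydrophobicity(hn, core_hydrophobicity(bp, t$res_types, scale))
      }, numeric(1))
    )
  })
}

#' Bin core-hydrophobicity differences by LDDT
#'
#' Buckets (deltaH, LDDT) samples into the given LDDT bins and reports per
#' bin the sample count and the fraction with deltaH < 0 (models whose core
#' is more hydrophobic than native). The pooled fraction over all samples
#' with LDDT < 0.8 (wrong-fold models) is attached as an attribute.
#'
#' @param deltas A tibble with columns `delta_h` and `lddt` (e.g. from
#'   [delta_h_table()]).
#' @param bin_edges Increasing LDDT bin edges covering \[0, 1\].
#' @return A `binned_delta_h` tibble: `bin_lo`, `bin_hi`, `n`,
#'   `frac_negative`; attributes `samples` (per-bin deltaH lists) and
#'   `frac_negative_low_lddt`.
#' @export
binned_delta_h <- function(deltas, bin_edges = seq(0, 1, by = 0.1)) {
  if (nrow(deltas) == 0) abort("empty input")
  if (bin_edges[1] > 0 || bin_edges[length(bin_edges)] < 1) {
    abort("bin edges must cover [0, 1]")
  }
  nb <- length(bin_edges) - 1
  bin <- pmin(pmax(findInterval(deltas$lddt, bin_edges,
                                rightmost.closed = TRUE), 1), nb)
  samples <- lapply(seq_len(nb), function(b) deltas$delta_h[bin == b])
  out <- tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    n = lengths(samples),
    frac_negative = vapply(samples, function(v) {
      if (length(v)) mean(v < 0) else NA_real_
    }, numeric(1))
  )
  attr(out, "samples") <- samples
  low <- deltas$delta_h[deltas$lddt < 0.8]
  attr(out, "frac_negative_low_lddt") <-
    if (length(low)) mean(low < 0) else NA_real_
  class(out) <- c("binned_delta_h", class(tibble::tibble()))
  out
}
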