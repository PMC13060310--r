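# Information accounting: per-label information iota(x) = -log2 p(x) from a
# reference corpus, flattened-LDDT bootstrap Spearman correlations, random
# restraint subsampling, correlation-versus-information curves and the I*
# (bits per residue to reach a target correlation) summary.

#' Fit an empirical information model over a label corpus
#'
#' Pooled outcome frequencies across the corpus define `p(x)` and the
#' per-label information `iota(x) = -log2 p(x)` in bits. Frequencies are exact
#' when every outcome of the alphabet is observed; if any outcome has zero
#' count, a Jeffreys pseudo-count of 0.5 is added to every outcome so that
#' iota stays finite.
#'
#' @param corpus A list of [label_set()]s (or bare label vectors) sharing one
#'   alphabet.
#' @param alphabet Alphabet; inferred from the first label set when omitted.
#' @return An `information_model`: tibble of `outcome`, `count`, `p`, `iota`
#'   with the alphabet as an attribute.
#' @export
fit_information <- function(corpus, alphabet = NULL) {
  if (!is.list(corpus)) corpus <- list(corpus)
  if (length(corpus) == 0L || sum(lengths(corpus)) == 0L) {
    abort("corpus must contain at least one label")
  }
  if (is.null(alphabet)) {
    alphabet <- attr(corpus[[1]], "alphabet") %||%
      sort(unique(unlist(lapply(corpus, as.character))))
  }
  pooled <- factor(unlist(lapply(corpus, as.character)), levels = alphabet)
  counts <- as.numeric(table(pooled))
  eff <- counts
  if (any(counts == 0)) eff <- counts + 0.5
  p <- eff / sum(eff)
  out <- tibble::tibble(outcome = alphabet, count = counts, p = p,
                        iota = -log2(p))
  attr(out, "alphabet") <- alphabet
  class(out) <- c("information_model", class(tibble::tibble()))
  out
}

#' @export
tidy.information_model <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("outcome", "count", "p", "iota")])
}

# iota values for a label vector under a fitted model
iota_of <- function(model, labels) {
  m <- match(as.character(labels), model$outcome)
  if (anyNA(m)) abort("label outside the information model's alphabet")
  model$iota[m]
}

#' Flattened-LDDT bootstrap Spearman correlation
#'
#' Benchmark decoy sets are dominated by low-accuracy models; a plain rank
#' correlation mostly reflects them. The flattened estimate divides LDDT into
#' `n_bins` equal-width bins over \[0, 1\], draws the same number of samples
#' (the smallest non-empty bin count) with replacement from every non-empty
#' bin, computes Spearman's rho per replicate (average ranks on ties) and
#' reports the median over `n_boot` replicates.
#'
#' @param phi_values,lddt_values Equal-length numeric vectors (one entry per
#'   decoy).
#' @param n_bins Number of equal-width LDDT bins (default 20).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the resampling; `NULL` uses the current RNG stream.
#' @return Numeric rho in \[-1, 1\]; attribute `degenerate` is `TRUE` (and
#'   rho 0) when all phi values are tied.
#' @export
flattened_spearman <- function(phi_values, lddt_values, n_bins = 20,
                               n_boot = 1000, seed = NULL) {
  if (length(phi_values) != length(lddt_values)) abort("length mismatch")
  if (length(phi_values) < 3) abort("need at least 3 observations")
  bin <- pmin(pmax(floor(lddt_values * n_bins) + 1, 1), n_bins)
  idx_by_bin <- split(seq_along(bin), bin)
  if (length(idx_by_bin) < 2) abort("need >= 2 non-empty LDDT bins")
  if (length(unique(phi_values)) == 1L) {
    return(structure(0, degenerate = TRUE))
  }
  m <- max(1L, min(lengths(idx_by_bin)))
  with_preserved_rng(seed, {
    # draw all replicate indices per bin at once: (m * n_boot) each
    draws <- lapply(idx_by_bin, function(ix) {
      matrix(ix[sample.int(length(ix), m * n_boot, replace = TRUE)], nrow = m)
    })
    rhos <- vapply(seq_len(n_boot), function(r) {
      take <- unlist(lapply(draws, function(d) d[, r]), use.names = FALSE)
      suppressWarnings(cor(phi_values[take], lddt_values[take],
                           method = "spearman"))
    }, numeric(1))
    structure(median(rhos, na.rm = TRUE), degenerate = FALSE)
  })
}

#' Random restraint subsampling of a label channel
#'
#' Passes a random fraction of the native labels per target (the restraints),
#' constructs the decoy labels at the same positions, scores every decoy with
#' the Matthews correlation over those positions only, and accounts the bits
#' spent: `I = sum(iota(native label at selected positions)) / N` per target
#' (N the residue count), averaged over targets.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param channel `"burial"`, `"contacts"`, `"ss"` or `"hbond"` (or any
#'   channel present in the benchmark).
#' @param fraction Fraction of positions to pass, in (0, 1\]; rounded half-up
#'   per target with a floor of one position.
#' @param info An [fit_information()] model for the channel; fitted on the
#'   benchmark's native labels when `NULL`.
#' @param seed Seed for the position draws.
#' @return A `restraint_draw` list: `scores` tibble (`target`, `decoy`,
#'   `phi`, `lddt`), per-target `selected` positions, total `n_r` and the
#'   bits-per-residue `I`.
#' @export
subsample_restraints <- function(benchmark, channel, fraction, info = NULL,
                                 seed = NULL) {
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  if (is.null(info)) info <- benchmark_information(benchmark, channel)
  k <- length(attr(info, "alphabet"))
  with_preserved_rng(seed, {
    per_target <- lapply(benchmark$targets, function(t) {
      nat <- channel_labels(t, channel, native = TRUE)
      L <- length(nat)
      n_take <- max(1L, min(L, as.integer(floor(L * fraction + 0.5))))
      sel <- sort(sample.int(L, n_take))
      nat_sel <- nat[sel]
      code_nat <- match(as.character(nat_sel), info$outcome)
      phis <- vapply(seq_len(nrow(t$decoys)), function(d) {
        dec <- channel_labels(t, channel, native = FALSE, decoy = d)[sel]
        code_dec <- match(as.character(dec), info$outcome)
        if (k == 2) {
          phi_pair_fast(code_nat - 1L, code_dec - 1L)
        } else {
          phi_multi_fast(code_nat, code_dec, k)
        }
      }, numeric(1))
      list(selected = sel,
           i_bits = sum(iota_of(info, nat_sel)) / t$n,
           scores = tibble::tibble(target = t$name, decoy = t$decoys$decoy_id,
                                   phi = phis, lddt = t$decoys$lddt))
    })
    out <- list(
      scores = dplyr::bind_rows(lapply(per_target, `[[`, "scores")),
      selected = lapply(per_target, `[[`, "selected"),
      n_r = sum(vapply(per_target, function(p) length(p$selected), integer(1))),
      I = mean(vapply(per_target, `[[`, numeric(1), "i_bits"))
    )
    class(out) <- "restraint_draw"
    out
  })
}

#' Correlation-versus-information curve for a channel
#'
#' For each sampled label fraction, repeats [subsample_restraints()] until the
#' running mean of I is stable (relative change below 1%, after at least 25
#' draws) or `n_repeats` draws, computing per draw the flattened bootstrap
#' Spearman of decoy-level phi against LDDT, and reports the mean I and mean
#' rho across draws. Each fraction uses an independent stream derived from
#' `seed`, so fractions can be computed in any order with identical results.
#'
#' @inheritParams subsample_restraints
#' @param fractions Increasing label fractions in (0, 1].
#' @param n_repeats Maximum draws per fraction (default 25).
#' @param n_boot Bootstrap replicates inside [flattened_spearman()].
#' @param seed Master seed.
#' @return A `burial_curve` tibble: `fraction`, `n_r`, `i_bits`, `rho`,
#'   `n_draws`, with the channel name as an attribute.
#' @export
rho_vs_I_curve <- function(benchmark, channel, fractions, n_repeats = 25,
                           n_boot = 1000, seed = 1, info = NULL) {
  if (length(fractions) < 1) abort("need at least one fraction")
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  if (is.null(info)) info <- benchmark_information(benchmark, channel)
  rows <- purrr::map_dfr(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    f_seed <- (seed + 7919 * round(f * 1e6)) %% 2147483647
    i_vals <- numeric(0)
    rho_vals <- numeric(0)
    n_r <- NA_integer_
    for (r in seq_len(n_repeats)) {
      draw <- subsample_restraints(benchmark, channel, f, info = info,
                                   seed = f_seed + r)
      i_vals <- c(i_vals, draw$I)
      rho_vals <- c(rho_vals,
                    as.numeric(flattened_spearman(draw$scores$phi,
                                                  draw$scores$lddt,
                                                  n_boot = n_boot,
                                                  seed = f_seed + r)))
      n_r <- draw$n_r
      if (r >= 25 && r > 1) {
        prev <- mean(i_vals[seq_len(r - 1)])
        if (prev > 0 && abs(mean(i_vals) - prev) / prev < 0.01) break
      }
    }
    tibble::tibble(fraction = f, n_r = n_r, i_bits = mean(i_vals),
                   rho = mean(rho_vals), n_draws = length(i_vals))
  })
  attr(rows, "channel") <- channel
  class(rows) <- c("burial_curve", class(tibble::tibble()))
  rows
}

#' Bits per residue needed to reach a correlation threshold (I*)
#'
#' The smallest information I at which the curve's rho crosses the threshold,
#' linearly interpolated between the bracketing points; `NA` when the curve
#' never reaches the threshold.
#'
#' @param curve A [rho_vs_I_curve()] tibble (or any tibble with `i_bits` and
#'   `rho`).
#' @param rho_threshold Correlation considered sufficient (default 0.9).
#' @return Bits per residue (numeric), or `NA_real_` when never reached.
#' @export
i_star <- function(curve, rho_threshold = 0.9) {
  if (nrow(curve) == 0) abort("empty curve")
  cv <- curve[order(curve$i_bits), ]
  above <- which(cv$rho >= rho_threshold)
  if (length(above) == 0) return(NA_real_)
  a <- above[1]
  if (a == 1) return(cv$i_bits[1])
  i0 <- cv$i_bits[a - 1]; i1 <- cv$i_bits[a]
  r0 <- cv$rho[a - 1]; r1 <- cv$rho[a]
  if (r1 == r0) return(i1)
  i0 + (rho_threshold - r0) / (r1 - r0) * (i1 - i0)
}
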