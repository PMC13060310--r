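# Label-flip robustness of the burial channel, external-predictor evaluation,
# and core-hydrophobicity / per-type base-rate analyses.

#' Randomly flip binary core-identity labels
#'
#' Each position is flipped independently with probability `p`, starting from
#' the native labels; the realized flipped fraction is reported exactly.
#'
#' @param native Integer 0/1 burial labels.
#' @param p Per-position flip probability in \[0, 1\].
#' @param seed Seed for the flips.
#' @return A `flip_result` list: `perturbed` labels, realized `f_flip`, `p`.
#' @export
flip_labels <- function(native, p, seed = NULL) {
  if (p < 0 || p > 1) abort("p must be in [0, 1]")
  native <- as.integer(native)
  with_preserved_rng(seed, {
    flip <- runif(length(native)) < p
    out <- list(perturbed = ifelse(flip, 1L - native, native),
                f_flip = mean(flip), p = p)
    class(out) <- "flip_result"
    out
  })
}

#' Robustness of the burial correlation to label noise
#'
#' For each flip probability and repeat, perturbs every target's native
#' burial labels, rescores all decoys with the Matthews correlation against
#' the perturbed labels, and computes the flattened bootstrap Spearman with
#' LDDT. Decoy labels are never perturbed.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param p_values Flip probabilities in \[0, 1\].
#' @param n_repeats Random perturbations per p (default 20).
#' @param n_boot Bootstrap replicates inside [flattened_spearman()].
#' @param seed Master seed.
#' @return A `robustness_curve` tibble: `p`, `f_flip` (mean realized),
#'   `rho` (mean), `rho_sd` (one standard deviation across repeats).
#' @export
robustness_curve <- function(benchmark, p_values, n_repeats = 20,
                             n_boot = 1000, seed = 1) {
  if (any(p_values < 0 | p_values > 1)) abort("p values must be in [0, 1]")
  rows <- purrr::map_dfr(seq_along(p_values), function(pi) {
    p <- p_values[pi]
    p_seed <- (seed + 104729 * pi) %% 2147483647
    reps <- lapply(seq_len(n_repeats), function(r) {
      flips <- numeric(0)
      phis <- numeric(0)
      lddts <- numeric(0)
      for (ti in seq_along(benchmark$targets)) {
        t <- benchmark$targets[[ti]]
        fl <- flip_labels(t$native$burial, p, seed = p_seed + 13 * r + 1000 * ti)
        flips <- c(flips, fl$f_flip * t$n)
        phis <- c(phis, vapply(t$decoys$burial, function(bp) {
          phi_pair_fast(fl$perturbed, bp)
        }, numeric(1)))
        lddts <- c(lddts, t$decoys$lddt)
      }
      rho <- as.numeric(flattened_spearman(phis, lddts, n_boot = n_boot,
                                           seed = p_seed + r))
      c(f_flip = sum(flips) / sum(vapply(benchmark$targets, `[[`, numeric(1), "n")),
        rho = rho)
    })
    reps <- do.call(rbind, reps)
    tibble::tibble(p = p, f_flip = mean(reps[, "f_flip"]),
                   rho = mean(reps[, "rho"]),
                   rho_sd = if (n_repeats > 1) sd(reps[, "rho"]) else NA_real_)
  })
  class(rows) <- c("robustness_curve", class(tibble::tibble()))
  rows
}

#' Evaluate externally predicted native burial labels
#'
#' Plays the role of a sequence-based core-identity predictor: the predicted
#' native labels replace the true ones, giving one (f_flip, rho) point
#' comparable to the random-flip robustness curve.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param predicted_native A list (one entry per target, in benchmark order)
#'   of 0/1 label vectors aligned to each target.
#' @param n_boot,seed Passed to [flattened_spearman()].
#' @return A one-row tibble: `f_flip` (pooled mismatch fraction vs the true
#'   native labels) and `rho`.
#' @export
external_predictor_point <- function(benchmark, predicted_native,
                                     n_boot = 1000, seed = 1) {
  if (length(predicted_native) != length(benchmark$targets)) {
    abort("one predicted label vector per target is required")
  }
  mism <- 0; total <- 0
  phis <- numeric(0); lddts <- numeric(0)
  for (ti in seq_along(benchmark$targets)) {
    t <- benchmark$targets[[ti]]
    pred <- as.integer(as.character(predicted_native[[ti]]))
    if (length(pred) != t$n) {
      abort(sprintf("prediction for target %s has length %d, expected %d",
                    t$name, length(pred), t$n))
    }
    mism <- mism + sum(pred != t$native$burial)
    total <- total + t$n
    phis <- c(phis, vapply(t$decoys$burial, function(bp) {
      phi_pair_fast(pred, bp)
    }, numeric(1)))
    lddts <- c(lddts, t$decoys$lddt)
  }
  tibble::tibble(
    f_flip = mism / total,
    rho = as.numeric(flattened_spearman(phis, lddts, n_boot = n_boot, seed = seed))
  )
}

#' Hydrophobicity scales
#'
#' Named per-residue hydrophobicity tables. `"consensus"` is the Eisenberg
#' consensus scale (Eisenberg, Weiss, Terwilliger & Wilcox 1982/1984
#' normalized consensus values); `"kd"` is Kyte-Doolittle.
#'
#' @param name Scale identifier.
#' @return Named numeric vector over the 20 three-letter codes, with the
#'   scale name as an attribute.
#' @export
hydro_scale <- function(name = c("consensus", "kd")) {
  name <- match.arg(name)
  h <- switch(name,
    consensus = c(ALA = 0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90,
                  CYS = 0.29, GLN = -0.85, GLU = -0.74, GLY = 0.48,
                  HIS = -0.40, ILE = 1.38, LEU = 1.06, LYS = -1.50,
                  MET = 0.64, PHE = 1.19, PRO = 0.12, SER = -0.18,
                  THR = -0.05, TRP = 0.81, TYR = 0.26, VAL = 1.08),
    kd = c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
           GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
           LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
           SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)
  )
  attr(h, "scale") <- name
  h
}

#' Core hydrophobicity of a labeled structure
#'
#' `H = (1/N) sum_i h_i b_i`: the summed hydrophobicity of core residues,
#' normalized by the total residue count.
#'
#' @param burial Integer 0/1 burial labels.
#' @param types Three-letter residue types, same length.
#' @param scale Named hydrophobicity vector, see [hydro_scale()].
#' @return Numeric scalar with `scale` and `n` attributes.
#' @export
core_hydrophobicity <- function(burial, types, scale = hydro_scale()) {
  if (length(burial) != length(types)) abort("burial and types differ in length")
  miss <- setdiff(unique(types), names(scale))
  if (length(miss)) {
    abort(paste0("hydrophobicity scale missing type(s): ",
                 paste(miss, collapse = ", ")))
  }
  v <- sum(scale[types] * as.integer(burial)) / length(burial)
  structure(v, scale = attr(scale, "scale"), n = length(burial))
}

#' Native-minus-model core hydrophobicity difference
#'
#' `deltaH = H_native - H_model`; negative values mean the model buried a
#' more hydrophobic core than the native structure.
#'
#' @param native,model [core_hydrophobicity()] values computed with the same
#'   scale and residue count.
#' @return Numeric scalar.
#' @export
delta_hydrophobicity <- function(native, model) {
  sn <- attr(native, "scale"); sm <- attr(model, "scale")
  if (!is.null(sn) && !is.null(sm) && !identical(sn, sm)) {
    abort("core hydrophobicities computed with different scales")
  }
  nn <- attr(native, "n"); nm <- attr(model, "n")
  if (!is.null(nn) && !is.null(nm) && nn != nm) {
    abort("core hydrophobicities computed over different residue counts")
  }
  as.numeric(native) - as.numeric(model)
}

#' Per-residue-type burial base rates and prediction accuracy
#'
#' Pools native and predicted burial labels over positions and reports, for
#' each residue type: the probability of being core (`p_c`), the Shannon
#' entropy of the core/surface base rate `H = -p_c log2 p_c - p_s log2 p_s`
#' (with 0 log 0 = 0), the accuracy rate `R` at which that type's labels are
#' predicted correctly, and its hydrophobicity. Types never observed are
#' omitted with a warning.
#'
#' @param native,predicted Pooled integer 0/1 label vectors (aligned).
#' @param types Pooled three-letter residue types, same length.
#' @param scale Hydrophobicity scale.
#' @return A tibble: `res_name`, `n`, `p_c`, `entropy`, `accuracy`, `h`.
#' @export
type_rates <- function(native, predicted, types, scale = hydro_scale()) {
  if (length(native) != length(predicted) || length(native) != length(types)) {
    abort("native, predicted and types must have equal length")
  }
  missing_types <- setdiff(AA3, unique(types))
  if (length(missing_types)) {
    warn(paste0("residue type(s) never observed, omitted: ",
                paste(missing_types, collapse = ", ")))
  }
  ent <- function(p) {
    q <- c(p, 1 - p)
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  tibble::tibble(res_name = types, native = as.integer(native),
                 predicted = as.integer(predicted)) %>%
    group_by(.data$res_name) %>%
    summarise(n = dplyr::n(),
              p_c = mean(.data$native),
              entropy = ent(mean(.data$native)),
              accuracy = mean(.data$native == .data$predicted),
              .groups = "drop") %>%
    mutate(h = unname(scale[.data$res_name])) %>%
    arrange(dplyr::desc(.data$h))
}
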