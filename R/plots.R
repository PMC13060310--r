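# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_errorbar geom_col labs theme_minimal
NULL

#' Plot a correlation-versus-information curve
#'
#' @param object A [rho_vs_I_curve()] tibble.
#' @param rho_threshold Reference line (default 0.9).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.burial_curve <- function(object, rho_threshold = 0.9, ...) {
  ggplot(object, aes(x = .data$i_bits, y = .data$rho)) +
    geom_hline(yintercept = rho_threshold, linetype = "dotted") +
    geom_line() +
    geom_point() +
    labs(x = "information used I (bits per residue)",
         y = expression(paste("flattened Spearman ", rho)),
         title = attr(object, "channel")) +
    theme_minimal()
}

#' Plot a label-flip robustness curve
#'
#' @param object A [robustness_curve()] tibble.
#' @param rho_threshold Reference line (default 0.9).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.robustness_curve <- function(object, rho_threshold = 0.9, ...) {
  ggplot(object, aes(x = .data$f_flip, y = .data$rho)) +
    geom_hline(yintercept = rho_threshold, linetype = "dotted") +
    geom_errorbar(aes(ymin = .data$rho - .data$rho_sd,
                      ymax = .data$rho + .data$rho_sd), width = 0.005) +
    geom_line() +
    geom_point() +
    labs(x = expression(f[flip]),
         y = expression(paste("flattened Spearman ", rho))) +
    theme_minimal()
}

#' Plot binned core-hydrophobicity deviations
#'
#' @param object A [binned_delta_h()] tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.binned_delta_h <- function(object, ...) {
  df <- object[!is.na(object$frac_negative), ]
  df$bin <- sprintf("%.1f-%.1f", df$bin_lo, df$bin_hi)
  ggplot(df, aes(x = .data$bin, y = .data$frac_negative)) +
    geom_col() +
    labs(x = "LDDT bin",
         y = expression(paste("fraction with ", Delta * scriptstyle(H) < 0))) +
    theme_minimal()
}
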