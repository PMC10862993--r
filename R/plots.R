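# ggplot2 displays for the main result types.

#' Plot observed versus predicted outcomes
#'
#' Scatter of predicted against observed scores with the identity line,
#' the standard display for cross-validated prediction quality.
#'
#' @param object A `cpm_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cpm_cv <- function(object, ...) {
  p <- object$predictions
  ggplot2::ggplot(p, ggplot2::aes(x = .data$observed,
                                  y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Observed score", y = "Predicted score",
      title = sprintf("%s prediction (n = %d)",
                      if (object$kind == "loocv")
                        "Leave-one-out" else "External",
                      nrow(p)),
      subtitle = sprintf("MAE = %.2f, r = %.2f, R² = %.2f",
                         mae(p$observed, p$predicted),
                         pearson_r(p$observed, p$predicted),
                         cv_r2(p$observed, p$predicted))) +
    ggplot2::theme_minimal()
}

#' Plot a cross-session similarity matrix
#'
#' Heat map of the baseline-by-follow-up correlation matrix from a
#' fingerprinting run; a visible bright diagonal indicates identifiable
#' subjects.
#'
#' @param object A `fingerprint_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fingerprint_result <- function(object, ...) {
  df <- tidyr::expand_grid(baseline = seq_len(object$n),
                           followup = seq_len(object$n))
  df$similarity <- as.numeric(t(object$similarity))[
    (df$baseline - 1) * object$n + df$followup]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$followup,
                                   y = .data$baseline,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Follow-up session", y = "Baseline session",
                  fill = "r",
                  title = sprintf(
                    "Identification: %d/%d forward, %d/%d reverse",
                    object$k_fwd, object$n, object$k_rev, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot differential power across features
#'
#' Manhattan-style display of \eqn{-\log_{10}(p)} of the
#' differential-power statistic per feature, highlighting features that
#' are idiosyncratic to individuals.
#'
#' @param fp A `fingerprint_result` (with DP computed) or the tibble
#'   from [differential_power()].
#' @param alpha Significance line to draw.
#' @return A ggplot object.
#' @export
plot_differential_power <- function(fp, alpha = 0.05) {
  dp <- if (inherits(fp, "fingerprint_result")) tidy(fp) else fp
  dp$index <- seq_len(nrow(dp))
  ggplot2::ggplot(dp, ggplot2::aes(x = .data$index,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Feature index",
                  y = expression(-log[10](italic(p))),
                  title = "Differential power") +
    ggplot2::theme_minimal()
}
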