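#' Prediction-quality metrics
#'
#' The three quantities used to judge predicted against observed
#' outcomes:
#' \describe{
#'   \item{`mae()`}{mean absolute error, \eqn{\frac1n\sum_i |y_i -
#'     \hat y_i|}, in outcome units.}
#'   \item{`pearson_r()`}{simple Pearson correlation between observed
#'     and predicted values.}
#'   \item{`cv_r2()`}{the cross-validation form of the coefficient of
#'     determination, \eqn{R^2 = 1 - \sum_i (y_i-\hat y_i)^2 / \sum_i
#'     (y_i-\bar y)^2}, where \eqn{\bar y} is the mean of the observed
#'     values being evaluated.  This is not the square of `pearson_r()`
#'     and is negative whenever the predictions do worse than the
#'     observed mean.}
#' }
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A single number.
#' @name prediction-metrics
NULL

#' @rdname prediction-metrics
#' @export
mae <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 1L)
  mean(abs(observed - predicted))
}

#' @rdname prediction-metrics
#' @export
cv_r2 <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) abort("`observed` is constant; R^2 undefined.")
  1 - sum((observed - predicted)^2) / sst
}

#' @rdname prediction-metrics
#' @export
pearson_r <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 3L)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    abort("Correlation undefined for a constant vector.")
  }
  cor(observed, predicted)
}

check_pairs <- function(observed, predicted, min_n) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  if (length(observed) < min_n) {
    abort(sprintf("Need at least %d observation(s).", min_n))
  }
  if (anyNA(observed) || anyNA(predicted)) abort("Missing values.")
  invisible(TRUE)
}

#' Prediction metrics with bootstrap confidence intervals
#'
#' Computes MAE, Pearson r and cross-validated R^2 for a set of
#' observed/predicted pairs, with percentile bootstrap confidence
#' intervals: the pairs are resampled with replacement `n_boot` times,
#' all three metrics recomputed per replicate, and the interval taken
#' at the (2.5, 97.5) percentiles (for `level = 0.95`).  Replicates in
#' which the resampled observed vector is constant (r and R^2
#' undefined) are redrawn, up to 100 attempts each, so `n_boot` valid
#' replicates always enter the intervals; the number of redraws is
#' recorded.
#'
#' @param observed,predicted Numeric vectors, or a `cpm_cv` object in
#'   `observed` (its prediction table is used).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed; identical seeds give identical intervals.
#' @return A one-row `metrics_report` tibble: `mae`, `r`, `r2`, their
#'   `*_lo` / `*_hi` interval bounds, `n`, `n_boot`, `n_redrawn`.
#' @export
prediction_metrics <- function(observed, predicted = NULL, n_boot = 1000,
                               level = 0.95, seed = NULL) {
  if (inherits(observed, "cpm_cv")) {
    predicted <- observed$predictions$predicted
    observed <- observed$predictions$observed
  }
  check_pairs(observed, predicted, min_n = 2L)
  n <- length(observed)
  if (n < 5L) warn("Fewer than 5 pairs: bootstrap intervals unstable.")
  point <- c(mae = mae(observed, predicted),
             r = pearson_r(observed, predicted),
             r2 = cv_r2(observed, predicted))
  alpha <- (1 - level) / 2

  boot <- local_seed(seed, {
    reps <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("mae", "r", "r2")))
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(observed[idx]) > 0 && sd(predicted[idx]) > 0) break
        redrawn <- redrawn + 1L
        if (attempt == 100L) {
          abort("Could not draw a non-degenerate bootstrap replicate.")
        }
      }
      reps[b, ] <- c(mae(observed[idx], predicted[idx]),
                     pearson_r(observed[idx], predicted[idx]),
                     cv_r2(observed[idx], predicted[idx]))
    }
    list(reps = reps, redrawn = redrawn)
  })
  ci <- apply(boot$reps, 2, quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- tibble::tibble(
    mae = point[["mae"]], mae_lo = ci[1, "mae"], mae_hi = ci[2, "mae"],
    r = point[["r"]], r_lo = ci[1, "r"], r_hi = ci[2, "r"],
    r2 = point[["r2"]], r2_lo = ci[1, "r2"], r2_hi = ci[2, "r2"],
    n = n, n_boot = n_boot, n_redrawn = boot$redrawn)
  class(out) <- c("metrics_report", class(out))
  out
}

#' @describeIn cpm_loocv One-row summary of prediction quality (MAE,
#'   r, cross-validated R^2 with bootstrap CIs).
#' @param n_boot,level,seed Passed to [prediction_metrics()].
#' @exportS3Method generics::glance
glance.cpm_cv <- function(x, n_boot = 1000, level = 0.95, seed = NULL,
                          ...) {
  prediction_metrics(x$predictions$observed, x$predictions$predicted,
                     n_boot = n_boot, level = level, seed = seed)
}
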