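#' Normalize feature vectors so dot products are correlations
#'
#' Row-normalizes a subjects-by-features matrix: each row is centered
#' and divided by the root of its sum of squared deviations, so that
#' the dot product of any two normalized rows equals the Pearson
#' correlation of the raw rows.
#'
#' @param x Numeric matrix (rows = subject/session vectors).
#' @return Matrix of the same shape; rows sum to ~0 with unit sum of
#'   squares.
#' @export
normalize_features <- function(x) {
  x <- as_feature_matrix(x, "x")
  xc <- x - rowMeans(x)
  ss <- sqrt(rowSums(xc^2))
  if (any(ss == 0)) {
    bad <- rownames(x)[ss == 0] %||% which(ss == 0)
    abort(paste0("Constant feature vector for: ",
                 paste(bad, collapse = ", ")))
  }
  xc / ss
}

#' Per-feature contributions to a cross-session correlation
#'
#' Decomposes the Pearson correlation of two feature vectors into
#' additive per-feature terms: after normalizing each vector (see
#' [normalize_features()]), the contribution of feature e is the
#' product of the two normalized values at e, and the contributions
#' sum exactly to the correlation of the raw vectors.
#'
#' @param xb,xf Equal-length numeric vectors (e.g. one subject's
#'   baseline and follow-up edge vectors).
#' @return Numeric vector of per-feature contributions.
#' @export
phi_contributions <- function(xb, xf) {
  if (length(xb) != length(xf)) abort("Vectors must have equal length.")
  nb <- normalize_features(matrix(xb, 1))
  nf <- normalize_features(matrix(xf, 1))
  as.numeric(nb * nf)
}

#' Binomial p-value for identification accuracy
#'
#' Upper-tail probability of observing at least `k` correct subject
#' identifications out of `n` under chance matching with replacement,
#' i.e. \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, 1/n)},
#' evaluated in log space so extreme tails (p below 1e-300 territory)
#' remain accurate.
#'
#' @param k Number of correct identifications (0..n).
#' @param n Number of subjects.
#' @param log.p Return the natural log of the p-value.
#' @return The tail probability (or its log).
#' @export
binomial_identification_p <- function(k, n, log.p = FALSE) {
  k <- assert_count(k, "k")
  n <- assert_count(n, "n", min = 2L)
  if (k > n) abort("`k` cannot exceed `n`.")
  lp <- pbinom(k - 1L, n, 1 / n, lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Per-subject, per-feature chance-match probability estimates
#'
#' For each subject i and feature e, estimates the probability that the
#' feature's self-match contribution \eqn{\varphi_{ii}(e)} would be
#' matched or exceeded by chance across subjects:
#' \deqn{\hat P_i(e) = \Big[\sum_j I(\varphi_{ij}(e) \ge
#'   \varphi_{ii}(e)) + \sum_j I(\varphi_{ji}(e) \ge \varphi_{ii}(e))
#'   - 1\Big] / (2n - 1)}
#' Both sums include j = i (each contributing 1), offset by the -1, so
#' the estimate lies in \eqn{[1/(2n-1),\, 1]}: low values mark features
#' that are highly identifying for that subject.
#'
#' The full \eqn{\varphi} tensor is n^2 x M; it is processed in feature
#' blocks so the working set stays bounded, and the result does not
#' depend on the block size.
#'
#' @param baseline,followup Subjects-by-features matrices (same subject
#'   and feature order).
#' @param block_size Features per block (default 512).
#' @return Subjects-by-features matrix of \eqn{\hat P_i(e)} values.
#' @export
p_hat_matrix <- function(baseline, followup, block_size = 512L) {
  xb <- normalize_features(baseline)
  xf <- normalize_features(followup)
  if (!identical(dim(xb), dim(xf))) abort("Session matrices must match.")
  n <- nrow(xb)
  m <- ncol(xb)
  out <- matrix(NA_real_, n, m, dimnames = dimnames(xb))
  for (start in seq(1L, m, by = block_size)) {
    cols <- start:min(start + block_size - 1L, m)
    for (e in cols) {
      a <- xb[, e]
      b <- xf[, e]
      phi <- outer(a, b)            # phi[i, j] = a_i * b_j
      phii <- a * b
      # row sum compares phi[i, ] to phii[i]; column sum compares
      # phi[, i] to phii[i] (note the transposed broadcast)
      cnt <- rowSums(phi >= phii) +
        colSums(phi >= matrix(phii, n, n, byrow = TRUE)) - 1L
      out[, e] <- cnt / (2 * n - 1)
    }
  }
  out
}

#' Differential power of features for subject identification
#'
#' Aggregates the per-subject chance-match probabilities of a feature
#' into the differential-power statistic
#' \eqn{DP(e) = -2 \sum_i \ln \hat P_i(e)}.  Under the null that the
#' true match probabilities are uniform, each \eqn{-2\ln \hat P_i(e)}
#' is chi-squared with 2 degrees of freedom, so DP(e) is tested against
#' a chi-squared distribution with 2n degrees of freedom (upper tail).
#' Large DP marks features that are idiosyncratic to individuals.
#'
#' @param p_hat Subjects-by-features matrix from [p_hat_matrix()], or a
#'   numeric vector of one feature's \eqn{\hat P_i(e)} values.
#' @return Tibble with one row per feature: `feature_id`, `dp`,
#'   `p_value`.
#' @export
differential_power <- function(p_hat) {
  if (is.vector(p_hat)) p_hat <- matrix(p_hat, ncol = 1)
  if (any(p_hat <= 0) || any(p_hat > 1)) {
    abort("All probability estimates must lie in (0, 1].")
  }
  n <- nrow(p_hat)
  dp <- -2 * colSums(log(p_hat))
  tibble::tibble(
    feature_id = colnames(p_hat) %||% sprintf("f%05d", seq_along(dp)),
    dp = as.numeric(dp),
    p_value = pchisq(dp, df = 2 * n, lower.tail = FALSE))
}

#' Select features by differential power
#'
#' Thresholds the chi-squared p-values of the differential-power
#' statistic, yielding a feature mask usable as an alternative
#' first-stage selection in the predictive model
#' (`model_config(selection_mode = "dp", ...)`).
#'
#' @param dp_p Per-feature DP p-values.
#' @param alpha Threshold; features with `dp_p < alpha` are selected.
#' @return Logical mask.
#' @export
dp_select <- function(dp_p, alpha) {
  if (any(dp_p < 0 | dp_p > 1, na.rm = TRUE)) abort("Invalid p-values.")
  dp_p < alpha
}

#' Fingerprint subjects across two sessions
#'
#' Matches every subject's baseline feature vector to the most similar
#' follow-up vector (and vice versa) by Pearson correlation,
#' identification with replacement.  An identification is correct when
#' the best match belongs to the same subject; the count of correct
#' identifications in each direction is tested against the binomial
#' chance model (see [binomial_identification_p()]).  Also computes the
#' per-feature statistics: \eqn{\hat P_i(e)} ([p_hat_matrix()]) and the
#' differential power with chi-squared inference
#' ([differential_power()]).
#'
#' Ties in the best-match argmax are broken toward the lowest subject
#' index, with a warning (ties have probability ~0 for real-valued
#' data).
#'
#' @param baseline,followup Subjects-by-features matrices with the same
#'   subject and feature order.
#' @param compute_dp Compute the per-feature statistics (can be skipped
#'   for speed when only identification is wanted).
#' @param block_size Passed to [p_hat_matrix()].
#' @return Object of class `fingerprint_result` with elements
#'   `similarity` (n x n correlation matrix, baseline rows vs follow-up
#'   columns), `matches_fwd`, `matches_rev`, `k_fwd`, `k_rev`, `p_fwd`,
#'   `p_rev`, `n`, and (when `compute_dp`) `p_hat` and `dp` (tibble).
#' @export
fingerprint <- function(baseline, followup, compute_dp = TRUE,
                        block_size = 512L) {
  xb <- normalize_features(baseline)
  xf <- normalize_features(followup)
  if (!identical(dim(xb), dim(xf))) {
    abort("Baseline and follow-up must have identical dimensions.")
  }
  n <- nrow(xb)
  if (n < 2L) abort("Need at least 2 subjects.")
  similarity <- xb %*% t(xf)    # r_ij = Pearson(baseline_i, followup_j)
  dimnames(similarity) <- list(rownames(xb), rownames(xf))

  argmax_ties <- function(v) {
    m <- max(v)
    hits <- which(v >= m - 0)
    if (length(hits) > 1L) warn("Similarity tie; lowest index used.")
    hits[1L]
  }
  matches_fwd <- apply(similarity, 1, argmax_ties)
  matches_rev <- apply(similarity, 2, argmax_ties)
  k_fwd <- sum(matches_fwd == seq_len(n))
  k_rev <- sum(matches_rev == seq_len(n))

  res <- list(similarity = similarity,
              matches_fwd = matches_fwd, matches_rev = matches_rev,
              k_fwd = k_fwd, k_rev = k_rev,
              p_fwd = binomial_identification_p(k_fwd, n),
              p_rev = binomial_identification_p(k_rev, n),
              n = n)
  if (compute_dp) {
    res$p_hat <- p_hat_matrix(baseline, followup, block_size = block_size)
    res$dp <- differential_power(res$p_hat)
  }
  structure(res, class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> n = %d subjects\n", x$n))
  cat(sprintf("  forward:  %d/%d correct (%.1f%%), p = %.3g\n",
              x$k_fwd, x$n, 100 * x$k_fwd / x$n, x$p_fwd))
  cat(sprintf("  reverse:  %d/%d correct (%.1f%%), p = %.3g\n",
              x$k_rev, x$n, 100 * x$k_rev / x$n, x$p_rev))
  invisible(x)
}

#' @describeIn fingerprint Per-feature differential-power table as a
#'   tibble.
#' @param x A `fingerprint_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fingerprint_result <- function(x, ...) {
  if (is.null(x$dp)) abort("Run fingerprint() with compute_dp = TRUE.")
  x$dp
}

#' @describeIn fingerprint One-row identification summary
#'   (`k_fwd`, `k_rev`, `n`, accuracies, binomial p-values).
#' @exportS3Method generics::glance
glance.fingerprint_result <- function(x, ...) {
  tibble::tibble(n = x$n, k_fwd = x$k_fwd, k_rev = x$k_rev,
                 accuracy_fwd = x$k_fwd / x$n,
                 accuracy_rev = x$k_rev / x$n,
                 p_fwd = x$p_fwd, p_rev = x$p_rev)
}
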