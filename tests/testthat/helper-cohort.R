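# Small cohort builders shared across test files.

quick_spec <- function(n_subjects = 20, n_nodes = 10,
                       signal_feature_count = 5, seed = 1, ...) {
  cohort_spec(n_subjects = n_subjects, n_nodes = n_nodes,
              signal_feature_count = signal_feature_count,
              seed = seed, ...)
}

# strong-signal, low-noise regime: prediction should clearly work.
# with K iid signal features, each feature's correlation with the
# outcome is capped near 1/sqrt(K), so the signal is kept sparse
signal_spec <- function(seed = 1, n_subjects = 60) {
  cohort_spec(n_subjects = n_subjects, n_nodes = 15,
              signal_feature_count = 5,
              sigma_subject = 1, sigma_session = 0.2,
              beta_signal = 8, beta_age = 0, beta_sex = 0,
              beta_baseline = 0, intercept = 12,
              sigma_outcome = 0.5, seed = seed)
}

# no subject component, no outcome signal: everything is exchangeable
null_spec <- function(seed = 1, n_subjects = 20, n_nodes = 8) {
  cohort_spec(n_subjects = n_subjects, n_nodes = n_nodes,
              sigma_subject = 0, sigma_session = 1,
              signal_feature_count = 0, seed = seed)
}

# independent oracle for partial correlation: regress each pair on all
# remaining nodes, correlate the residuals
partial_cor_oracle <- function(tc) {
  v <- ncol(tc)
  out <- diag(1, v)
  for (a in seq_len(v - 1)) {
    for (b in (a + 1):v) {
      others <- cbind(1, tc[, -c(a, b), drop = FALSE])
      ra <- stats::lsfit(others, tc[, a], intercept = FALSE)$residuals
      rb <- stats::lsfit(others, tc[, b], intercept = FALSE)$residuals
      out[a, b] <- out[b, a] <- cor(ra, rb)
    }
  }
  out
}

# independent oracle for P-hat: literal double loop over the indicator
# sums of the defining formula
p_hat_oracle <- function(baseline, followup) {
  nb <- connpredict::normalize_features(baseline)
  nf <- connpredict::normalize_features(followup)
  n <- nrow(nb)
  m <- ncol(nb)
  out <- matrix(NA_real_, n, m)
  for (e in seq_len(m)) {
    for (i in seq_len(n)) {
      phi_ii <- nb[i, e] * nf[i, e]
      s1 <- sum(vapply(seq_len(n),
                       function(j) nb[i, e] * nf[j, e] >= phi_ii,
                       logical(1)))
      s2 <- sum(vapply(seq_len(n),
                       function(j) nb[j, e] * nf[i, e] >= phi_ii,
                       logical(1)))
      out[i, e] <- (s1 + s2 - 1) / (2 * n - 1)
    }
  }
  out
}
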