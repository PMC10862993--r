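test_that("identification recovers identical and shifted sessions", {
  set.seed(7)
  x <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("s%02d", 1:10), NULL))
  fp <- fingerprint(x, x, compute_dp = FALSE)
  expect_identical(fp$k_fwd, 10L)
  expect_identical(fp$k_rev, 10L)
  # cyclic shift: nobody matches themselves
  shifted <- x[c(2:10, 1), ]
  rownames(shifted) <- rownames(x)
  fp0 <- fingerprint(x, shifted, compute_dp = FALSE)
  expect_identical(fp0$k_fwd, 0L)
  expect_identical(fp0$k_rev, 0L)
  # similarity is the plain Pearson correlation of the raw vectors
  expect_equal(fp$similarity[1, 2], cor(x[1, ], x[2, ]),
               tolerance = 1e-12)
  x_bad <- x
  x_bad[3, ] <- 2                  # one subject with a flat vector
  expect_error(fingerprint(x_bad, x), "[Cc]onstant")
})

test_that("binomial identification p-values are computed in log space", {
  # printed analytic tails for n = 66 subjects
  expect_equal(signif(binomial_identification_p(53, 66), 2), 6.2e-84)
  expect_equal(signif(binomial_identification_p(56, 66), 2), 2.3e-91)
  expect_equal(binomial_identification_p(0, 20), 1)
  expect_equal(binomial_identification_p(1, 20),
               1 - (1 - 1 / 20)^20, tolerance = 1e-12)
  # monotone decreasing in k
  p_seq <- vapply(0:20, binomial_identification_p, numeric(1), n = 20)
  expect_true(all(diff(p_seq) < 0))
  expect_error(binomial_identification_p(21, 20), "exceed")
  # log version stays finite where the plain value underflows
  expect_true(is.finite(binomial_identification_p(500, 500,
                                                  log.p = TRUE)))
})

test_that("phi contributions decompose the correlation exactly", {
  xb <- c(0.2, -1.3, 0.5, 2.0)
  xf <- c(1.0, -0.6, 0.1, 1.4)
  phi <- phi_contributions(xb, xf)
  expect_length(phi, 4)
  expect_equal(sum(phi), cor(xb, xf), tolerance = 1e-12)
  # hand computation of the first term
  nb <- (xb - mean(xb)) / sqrt(sum((xb - mean(xb))^2))
  nf <- (xf - mean(xf)) / sqrt(sum((xf - mean(xf))^2))
  expect_equal(phi[1], nb[1] * nf[1], tolerance = 1e-12)
  expect_equal(sum(phi_contributions(xb, xb)), 1, tolerance = 1e-12)
  expect_error(phi_contributions(xb, xf[1:3]), "length")
})

test_that("self-correlations equal the summed phi across all pairs", {
  set.seed(8)
  b <- matrix(rnorm(6 * 20), 6, 20)
  f <- matrix(rnorm(6 * 20), 6, 20)
  fp <- fingerprint(b, f)
  nb <- normalize_features(b)
  nf <- normalize_features(f)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(fp$similarity[i, j], sum(nb[i, ] * nf[j, ]),
                 tolerance = 1e-10)
  }
})

test_that("P-hat matches the indicator-sum oracle and its bounds", {
  set.seed(9)
  b <- matrix(rnorm(5 * 12), 5, 12)
  f <- matrix(rnorm(5 * 12), 5, 12)
  got <- p_hat_matrix(b, f)
  expect_equal(got, p_hat_oracle(b, f), ignore_attr = TRUE,
               tolerance = 1e-12)
  n <- 5
  expect_true(all(got >= 1 / (2 * n - 1) - 1e-12))
  expect_true(all(got <= 1 + 1e-12))
  # block size must not matter
  expect_equal(p_hat_matrix(b, f, block_size = 3L), got)
  expect_equal(p_hat_matrix(b, f, block_size = 1000L), got)
})

test_that("P-hat attains its extremes for dominant self-matches", {
  # rows normalize to (+-0.707, -+0.707, 0); at feature 1, subject 1's
  # self-product is +0.5 while every cross-product is -0.5
  n <- 4
  up <- c(2, 0, 1)     # normalizes to ( 0.707, -0.707, 0)
  dn <- c(0, 2, 1)     # normalizes to (-0.707,  0.707, 0)
  b <- rbind(up, dn, dn, dn)
  f <- rbind(up, dn, dn, dn)
  got <- p_hat_matrix(b, f)
  expect_equal(unname(got[1, 1]), 1 / (2 * n - 1))
  # flipped self-match: subject 1's self-product is strictly smallest
  b2 <- rbind(up, dn, dn, dn)
  f2 <- rbind(dn, up, up, up)
  got2 <- p_hat_matrix(b2, f2)
  expect_equal(unname(got2[1, 1]), 1)
})

test_that("differential power follows the chi-squared closed form", {
  expect_equal(differential_power(rep(1, 5))$dp, 0)
  expect_equal(differential_power(rep(1, 5))$p_value, 1)
  # n = 2, P-hat = (e^-1, e^-1): DP = 4, chi^2_4 survival at 4 is
  # exp(-2) * (1 + 2)
  d <- differential_power(c(exp(-1), exp(-1)))
  expect_equal(d$dp, 4, tolerance = 1e-12)
  expect_equal(d$p_value, exp(-2) * 3, tolerance = 1e-12)
  expect_error(differential_power(c(0.5, 0)), "probability")
})

test_that("dp_select thresholds the p-values", {
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_identical(dp_select(p, 0), rep(FALSE, 4))
  expect_identical(dp_select(p, 1), rep(TRUE, 4))
  expect_identical(dp_select(p, 0.05), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(dp_select(c(0.5, 1.2), 0.05), "p-values")
})

test_that("empirical DP p-values under a null generator are conservative", {
  # the plug-in P-hat is discrete and dependent across subjects, so its
  # chi-squared p-values sit above uniform; the mean should exceed 0.5
  co <- generate_cohort(null_spec(seed = 55, n_subjects = 30,
                                  n_nodes = 12))
  fp <- fingerprint(co$baseline, co$followup)
  expect_gt(mean(fp$dp$p_value), 0.5)
  expect_true(all(fp$dp$dp >= 0))
})

test_that("DP-selected and CPM-selected feature sets are reported jointly", {
  co <- generate_cohort(signal_spec(seed = 20))
  fp <- fingerprint(co$baseline, co$followup)
  sel <- first_stage_select(co$baseline, co$phenotypes$outcome_post)
  dp_mask <- dp_select(fp$dp$p_value, 0.05)
  cpm_mask <- sel$selected_pos | sel$selected_neg
  overlap <- sum(dp_mask & cpm_mask)
  # no equality asserted: the two criteria capture different variance
  expect_true(overlap >= 0 && overlap <= min(sum(dp_mask),
                                             sum(cpm_mask)))
  # dp-mode config plugs into the predictive pipeline
  cfg <- model_config(selection_mode = "dp", dp_alpha = 0.5,
                      dp_p = fp$dp$p_value)
  cv <- suppressWarnings(cpm_loocv(co$baseline, co$phenotypes, cfg))
  expect_identical(nrow(cv$predictions), nrow(co$phenotypes))
})

test_that("tidy and glance summarize a fingerprint result", {
  co <- generate_cohort(quick_spec(seed = 13))
  fp <- fingerprint(co$baseline, co$followup)
  g <- glance(fp)
  expect_identical(g$n, nrow(co$baseline))
  expect_equal(g$accuracy_fwd, g$k_fwd / g$n)
  td <- tidy(fp)
  expect_identical(nrow(td), ncol(co$baseline))
  expect_named(td, c("feature_id", "dp", "p_value"))
})
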