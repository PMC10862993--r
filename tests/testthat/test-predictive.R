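test_that("first-stage correlations match the cor.test oracle", {
  set.seed(14)
  x <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(10)
  sel <- first_stage_select(x, y, alpha_select = 0.05)
  for (j in 1:5) {
    ct <- cor.test(x[, j], y)
    expect_equal(sel$r[j], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(sel$p[j], ct$p.value, tolerance = 1e-10)
  }
  expect_false(any(sel$selected_pos & sel$selected_neg))
})

test_that("selection thresholds behave at the extremes", {
  set.seed(15)
  x <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  x[, 2] <- y                       # feature identical to the outcome
  sel <- first_stage_select(x, y, alpha_select = 0.01)
  expect_true(sel$selected_pos[2])
  expect_lt(sel$p[2], 1e-12)
  all_in <- first_stage_select(x, y, alpha_select = 1.0)
  expect_true(all(all_in$selected_pos | all_in$selected_neg))
  # shrinking alpha never grows the selection
  alphas <- c(1, 0.5, 0.1, 0.01, 0.001)
  counts <- vapply(alphas, function(a) {
    s <- first_stage_select(x, y, alpha_select = a)
    sum(s$selected_pos) + sum(s$selected_neg)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("first-stage partial correlation conditions on covariates", {
  set.seed(16)
  n <- 30
  z <- cbind(age = rnorm(n))
  y <- rnorm(n) + 2 * z[, 1]
  x <- matrix(rnorm(n * 3), n, 3)
  x[, 1] <- z[, 1] + rnorm(n, 0, 0.05)  # related to y only through age
  sel <- first_stage_select(x, y, covariates = z)
  # oracle: t-test on the feature coefficient in lm(y ~ feature + age)
  for (j in 1:3) {
    fit <- summary(lm(y ~ x[, j] + z[, 1]))
    expect_equal(sel$p[j], fit$coefficients[2, 4], tolerance = 1e-8)
  }
  expect_error(first_stage_select(x, rep(1, n)), "constant")
})

test_that("feature summaries sum the selected features", {
  feats <- rbind(c(1.5, 2.5, 10), c(0, 1, 2))
  sel <- tibble::tibble(feature_id = paste0("f", 1:3),
                        r = c(0.5, -0.5, 0.9),
                        p = c(0.001, 0.001, 0.5),
                        selected_pos = c(TRUE, FALSE, FALSE),
                        selected_neg = c(FALSE, TRUE, FALSE))
  cfg <- model_config("both")
  s <- summarize_features(feats, sel, cfg)
  expect_equal(s[, "sum_pos"], c(1.5, 0), ignore_attr = TRUE)
  expect_equal(s[, "sum_neg"], c(2.5, 1), ignore_attr = TRUE)
  # r-weighted: (0.5, -0.5) on values (2, 2) in one mask -> 1 - 1 = 0;
  # with only the first selected -> 1.0
  sel2 <- sel
  sel2$selected_pos <- c(TRUE, TRUE, FALSE)
  sw <- summarize_features(rbind(c(2, 2, 0)), sel2,
                           model_config("positive",
                                        weighting = "r_weighted"))
  expect_equal(sw[1, "sum_pos"], 0.5 * 2 + (-0.5) * 2, ignore_attr = TRUE)
  sw1 <- summarize_features(rbind(c(2, 2, 0)), sel,
                            model_config("positive",
                                         weighting = "r_weighted"))
  expect_equal(sw1[1, "sum_pos"], 1.0, ignore_attr = TRUE)
  # empty mask warns and yields zeros
  sel3 <- sel
  sel3$selected_neg <- rep(FALSE, 3)
  expect_warning(s3 <- summarize_features(feats, sel3,
                                          model_config("both")),
                 "Empty")
  expect_equal(s3[, "sum_neg"], c(0, 0), ignore_attr = TRUE)
})

test_that("the second stage recovers exact linear relations", {
  s <- matrix(seq(1, 10), ncol = 1, dimnames = list(NULL, "sum_pos"))
  y <- 2 * s[, 1] + 3
  fit <- fit_second_stage(s, y, config = model_config())
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-10)
  # duplicated covariate: rank-deficiency error
  z <- cbind(age = rnorm(10), age2 = 0)
  z[, 2] <- z[, 1]
  cfg <- model_config(covariate_role = "predictors",
                      covariates = "age")
  expect_error(fit_second_stage(s, y, z, cfg), "rank deficient")
})

test_that("nuisance and predictor schemes agree in sample (FWL)", {
  set.seed(18)
  n <- 40
  co <- generate_cohort(signal_spec(seed = 18, n_subjects = n))
  y <- co$phenotypes$outcome_post
  covs <- cbind(age = co$phenotypes$age, sex = co$phenotypes$sex)
  sel <- first_stage_select(co$baseline, y, covariates = covs)
  cfg_p <- model_config(covariate_role = "predictors",
                        covariates = c("age", "sex"))
  cfg_n <- model_config(covariate_role = "nuisance",
                        covariates = c("age", "sex"))
  s <- summarize_features(co$baseline, sel, cfg_p)
  fit_p <- fit_second_stage(s, y, covs, cfg_p, selection = sel)
  fit_n <- fit_second_stage(s, y, covs, cfg_n, selection = sel)
  # identical slopes for the feature sums
  expect_equal(fit_p$coefficients[["sum_pos"]],
               fit_n$coefficients[["sum_pos"]], tolerance = 1e-8)
  # identical in-sample predictions
  pr_p <- predict(fit_p, co$baseline, co$phenotypes)
  pr_n <- predict(fit_n, co$baseline, co$phenotypes,
                  nuisance_source = "train")
  expect_equal(pr_p, pr_n, tolerance = 1e-8)
  # and both reproduce the OLS fitted values
  ols <- lm(y ~ s + covs)
  expect_equal(pr_p, unname(fitted(ols)), tolerance = 1e-8)
})

test_that("prediction validates its inputs", {
  co <- generate_cohort(quick_spec(seed = 3))
  y <- co$phenotypes$outcome_post
  sel <- first_stage_select(co$baseline, y, alpha_select = 0.5)
  cfg <- model_config()
  s <- summarize_features(co$baseline, sel, cfg)
  fit <- fit_second_stage(s, y, config = cfg, selection = sel)
  expect_error(predict(fit, co$baseline[, 1:10]), "mismatch")
  cfg_n <- model_config(covariate_role = "nuisance", covariates = "age")
  covs <- build_cov <- cbind(age = co$phenotypes$age)
  sel_n <- first_stage_select(co$baseline, y, covariates = covs)
  s_n <- suppressWarnings(summarize_features(co$baseline, sel_n, cfg_n))
  fit_n <- fit_second_stage(s_n, y, covs, cfg_n, selection = sel_n)
  expect_error(predict(fit_n, co$baseline[1, , drop = FALSE],
                       co$phenotypes[1, ], nuisance_source = "test"),
               "train")
})

test_that("LOOCV predicts a noiseless signal cohort almost perfectly", {
  co <- generate_cohort(cohort_spec(n_subjects = 60, n_nodes = 15,
                                    signal_feature_count = 4,
                                    sigma_subject = 1, sigma_session = 0.1,
                                    beta_signal = 5, sigma_outcome = 0,
                                    beta_age = 0, beta_sex = 0,
                                    beta_baseline = 0, intercept = 12,
                                    seed = 77))
  cv <- cpm_loocv(co$baseline, co$phenotypes,
                  model_config(selection_mode = "both"))
  r <- pearson_r(cv$predictions$observed, cv$predictions$predicted)
  expect_gt(r, 0.9)
})

test_that("LOOCV predictions do not depend on subject order", {
  co <- generate_cohort(quick_spec(n_subjects = 16, seed = 9))
  cfg <- model_config(alpha_select = 0.1)
  cv1 <- suppressWarnings(cpm_loocv(co$baseline, co$phenotypes, cfg))
  perm <- sample(16)
  cv2 <- suppressWarnings(
    cpm_loocv(co$baseline[perm, ], co$phenotypes[perm, ], cfg))
  a <- cv1$predictions[order(cv1$predictions$subject_id), ]
  b <- cv2$predictions[order(cv2$predictions$subject_id), ]
  expect_equal(a$predicted, b$predicted, tolerance = 1e-10)
})

test_that("tiny samples run via the fallback with a warning", {
  co <- generate_cohort(quick_spec(n_subjects = 3, n_nodes = 5,
                                   signal_feature_count = 0, seed = 2))
  w <- capture_warnings(
    cv <- cpm_loocv(co$baseline, co$phenotypes, model_config()))
  expect_true(any(grepl("Small sample", w)))
  expect_identical(nrow(cv$predictions), 3L)
  # two-subject training folds cannot select features: every fold
  # falls back to the intercept-only model
  expect_true(all(cv$predictions$fallback))
})

test_that("external validation on the training set is in-sample", {
  co <- generate_cohort(signal_spec(seed = 4, n_subjects = 30))
  cfg <- model_config()
  ext <- cpm_external(co$baseline, co$phenotypes,
                      co$baseline, co$phenotypes, cfg)
  y <- co$phenotypes$outcome_post
  sel <- first_stage_select(co$baseline, y,
                            alpha_select = cfg$alpha_select)
  s <- summarize_features(co$baseline, sel, cfg)
  fit <- fit_second_stage(s, y, config = cfg, selection = sel)
  expect_equal(ext$predictions$predicted,
               predict(fit, co$baseline), tolerance = 1e-10)
  expect_error(cpm_external(co$baseline, co$phenotypes,
                            co$baseline[, 1:10], co$phenotypes, cfg),
               "mismatch")
})

test_that("two cohorts from one truth validate externally", {
  # one generative draw split in half: both halves share the signal
  # features and coefficients but have independent subjects
  big <- generate_cohort(signal_spec(seed = 31, n_subjects = 120))
  a <- 1:60; b <- 61:120
  cfg <- model_config()
  cv <- cpm_loocv(big$baseline[a, ], big$phenotypes[a, ], cfg)
  r_loo <- pearson_r(cv$predictions$observed, cv$predictions$predicted)
  ext <- cpm_external(big$baseline[a, ], big$phenotypes[a, ],
                      big$baseline[b, ], big$phenotypes[b, ], cfg)
  r_ext <- pearson_r(ext$predictions$observed,
                     ext$predictions$predicted)
  expect_gt(r_loo, 0.5)
  expect_lt(abs(r_ext - r_loo), 0.15)
})

test_that("fold-frequency maps count selections per feature", {
  mask_pos <- matrix(FALSE, 10, 3,
                     dimnames = list(NULL, paste0("f", 1:3)))
  mask_pos[, 1] <- TRUE             # always selected
  mask_pos[1:3, 2] <- TRUE          # 3 of 10 folds
  fake <- structure(list(
    predictions = tibble::tibble(subject_id = as.character(1:10)),
    masks = list(positive = mask_pos,
                 negative = matrix(FALSE, 10, 3,
                                   dimnames = list(NULL,
                                                   paste0("f", 1:3)))),
    config = model_config(), kind = "loocv"), class = "cpm_cv")
  ff <- feature_frequency(fake, min_frac = 0.5)
  expect_identical(ff$feature_id, "f1")
  expect_equal(ff$fraction, 1.0)
  ff2 <- feature_frequency(fake, min_frac = 0.2)
  expect_true("f2" %in% ff2$feature_id)
  ext <- fake; ext$masks <- NULL
  expect_error(feature_frequency(ext), "LOOCV")
})

test_that("signal features dominate the LOOCV frequency map", {
  co <- generate_cohort(signal_spec(seed = 6))
  cv <- cpm_loocv(co$baseline, co$phenotypes,
                  model_config(selection_mode = "both"))
  ff <- feature_frequency(cv, min_frac = 0.5)
  truth <- co$truth$signal_features
  expect_gt(mean(ff$feature_id %in% truth), 0.5)
})

test_that("permutation motion check matches exhaustive enumeration", {
  set.seed(30)
  fd <- rnorm(5)
  y <- rnorm(5)
  ex <- motion_check(fd, y, exact = TRUE)
  mc <- motion_check(fd, y, n_perm = 100000, exact = FALSE, seed = 1)
  expect_equal(ex$p_value, mc$p_value, tolerance = 0.01)
  # x = y: |r| = 1 is attained only by the identity relabeling of
  # generic values, so p equals the minimal attainable 1/n!
  self <- motion_check(fd, fd + 0, exact = TRUE)
  expect_equal(self$p_value, 1 / factorial(5))
  expect_error(motion_check(rep(1, 5), y), "Constant")
})
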