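#' Configure a connectome / anatomical predictive model
#'
#' Collects the modeling choices for the two-stage predictive pipeline:
#' which features enter the model (sign of the first-stage association,
#' or a fingerprinting-derived differential-power mask), the first-stage
#' significance threshold, how covariates are handled, the outcome
#' definition, and optional correlation weighting of the feature sums.
#'
#' Covariate handling follows three schemes.  `"none"` uses only the
#' feature sums.  `"predictors"` adds the covariates as ordinary
#' regressors in the second stage.  `"nuisance"` residualizes both the
#' outcome and the feature sums with respect to the covariates before
#' the second-stage fit; at prediction time the test data are
#' residualized with nuisance coefficients taken either from the
#' training set (the only option in leave-one-out cross-validation) or
#' re-estimated from the test set (external validation), and the
#' nuisance-predicted component is always added back so predictions stay
#' on the original outcome scale.  In all schemes with covariates, the
#' first-stage association is the partial correlation of each feature
#' with the outcome given the covariates.
#'
#' @param selection_mode `"positive"`, `"negative"`, `"both"` (two sum
#'   predictors), or `"dp"` (features pre-selected by differential
#'   power; requires `dp_p`).
#' @param alpha_select Two-sided p-value threshold for first-stage
#'   feature selection (default 0.01).
#' @param covariate_role `"none"`, `"predictors"` or `"nuisance"`.
#' @param covariates Character subset of
#'   `c("age", "sex", "scanner", "outcome_baseline")`.
#' @param outcome_def `"post"` (post-treatment score) or `"change"`
#'   (post minus baseline; negative = improvement).
#' @param weighting `"none"` or `"r_weighted"` (each selected feature is
#'   multiplied by its training-set correlation before summing).
#' @param dp_alpha Threshold applied to `dp_p` in `"dp"` mode.
#' @param dp_p Per-feature differential-power p-values (from
#'   [fingerprint()] / [differential_power()]), required for `"dp"`
#'   mode.
#' @return An object of class `model_config`.
#' @export
model_config <- function(selection_mode = c("positive", "negative",
                                            "both", "dp"),
                         alpha_select = 0.01,
                         covariate_role = c("none", "predictors",
                                            "nuisance"),
                         covariates = character(),
                         outcome_def = c("post", "change"),
                         weighting = c("none", "r_weighted"),
                         dp_alpha = 0.05,
                         dp_p = NULL) {
  selection_mode <- match.arg(selection_mode)
  covariate_role <- match.arg(covariate_role)
  outcome_def <- match.arg(outcome_def)
  weighting <- match.arg(weighting)
  assert_scalar_number(alpha_select, "alpha_select", min = 0)
  if (alpha_select > 1) abort("`alpha_select` must be in [0, 1].")
  allowed <- c("age", "sex", "scanner", "outcome_baseline")
  if (length(covariates) && !all(covariates %in% allowed)) {
    abort(paste0("`covariates` must be a subset of: ",
                 paste(allowed, collapse = ", ")))
  }
  if (covariate_role != "none" && length(covariates) == 0L) {
    abort("`covariate_role` requires at least one covariate.")
  }
  if (selection_mode == "dp" && is.null(dp_p)) {
    abort(paste0("selection_mode = \"dp\" requires `dp_p`; run the ",
                 "fingerprinting analysis first."))
  }
  structure(
    list(selection_mode = selection_mode, alpha_select = alpha_select,
         covariate_role = covariate_role, covariates = covariates,
         outcome_def = outcome_def, weighting = weighting,
         dp_alpha = dp_alpha, dp_p = dp_p),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config> %s edges, alpha = %g, covariates = %s (%s), outcome = %s\n",
    x$selection_mode, x$alpha_select,
    if (length(x$covariates)) paste(x$covariates, collapse = "+") else "none",
    x$covariate_role, x$outcome_def))
  invisible(x)
}

# Outcome vector implied by the config.
outcome_from <- function(phenotypes, config) {
  y <- phenotypes$outcome_post
  if (config$outcome_def == "change") y <- y - phenotypes$outcome_baseline
  as.numeric(y)
}

# Numeric covariate design (no intercept); scanner is dummy-coded
# against its first level.  NULL when no covariates are requested.
build_covariates <- function(phenotypes, covariates) {
  if (length(covariates) == 0L) return(NULL)
  cols <- list()
  for (v in covariates) {
    if (!v %in% names(phenotypes)) {
      abort(sprintf("Covariate `%s` missing from the phenotype table.", v))
    }
    if (v == "scanner") {
      f <- factor(phenotypes$scanner)
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0("scanner", levels(f)[-1])
        cols[[v]] <- mm
      }
    } else {
      cols[[v]] <- matrix(as.numeric(phenotypes[[v]]),
                          dimnames = list(NULL, v))
    }
  }
  if (length(cols) == 0L) return(NULL)
  do.call(cbind, cols)
}

#' First-stage feature selection by correlation with the outcome
#'
#' Correlates every feature with the outcome and splits significant
#' features by the sign of the association.  Without covariates this is
#' the Pearson correlation with a two-sided parametric p-value from the
#' t transform \eqn{t = r\sqrt{df}/\sqrt{1-r^2}}; with covariates it is
#' the partial correlation of feature and outcome given the covariates
#' (equivalent to the t-test on the feature coefficient in a joint
#' regression), with `df = n - 2 - k`.
#'
#' @param features Numeric subjects-by-features matrix.
#' @param outcome Numeric outcome vector.
#' @param covariates Optional numeric subjects-by-k covariate matrix.
#' @param alpha_select Two-sided selection threshold.
#' @return A `cpm_selection` tibble with one row per feature:
#'   `feature_id`, `r`, `p`, `selected_pos`, `selected_neg`.  Constant
#'   features get `r = 0`, `p = 1`.
#' @export
first_stage_select <- function(features, outcome, covariates = NULL,
                               alpha_select = 0.01) {
  features <- as_feature_matrix(features)
  n <- nrow(features)
  if (length(outcome) != n) abort("`outcome` length must match subjects.")
  if (n < 2L) abort("Need at least 2 subjects for feature selection.")
  if (sd(outcome) == 0) abort("`outcome` is constant.")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (k > 0L && k >= n - 2L) {
    abort("Too many covariates for the sample size.")
  }

  y <- as.numeric(outcome)
  x <- features
  if (k > 0L) {
    z <- cbind(1, as.matrix(covariates))
    qz <- qr(z)
    y <- as.numeric(qr.resid(qz, y))
    x <- qr.resid(qz, x)
  }
  xs <- matrixStats_sd(x)
  r <- rep(0, ncol(x))
  ok <- xs > 0 & sd(y) > 0
  if (any(ok)) {
    r[ok] <- as.numeric(cor(x[, ok, drop = FALSE], y))
  }
  df <- n - 2L - k
  p <- rep(1, ncol(x))
  if (df >= 1L) {
    tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))
    p[ok] <- 2 * pt(abs(tt[ok]), df, lower.tail = FALSE)
  }
  ids <- colnames(features) %||% sprintf("f%05d", seq_len(ncol(features)))
  out <- tibble::tibble(
    feature_id = ids, r = r, p = p,
    selected_pos = p < alpha_select & r > 0,
    selected_neg = p < alpha_select & r < 0)
  class(out) <- c("cpm_selection", class(out))
  attr(out, "alpha_select") <- alpha_select
  attr(out, "n") <- n
  attr(out, "df") <- df
  out
}

# Column SDs without an extra dependency.
matrixStats_sd <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

#' Summarize selected features into per-subject network scores
#'
#' Sums each subject's values over the selected feature masks, producing
#' the predictors for the second-stage regression: one column for
#' `"positive"`, `"negative"` or `"dp"` mode, two (positive and
#' negative sums) for `"both"`.  With `weighting = "r_weighted"` each
#' feature is multiplied by its training-set correlation before
#' summing.  An empty mask yields an all-zero column and a warning;
#' downstream fits fall back to a covariate-only model when no summary
#' carries information.
#'
#' @param features Numeric subjects-by-features matrix.
#' @param selection A `cpm_selection` from [first_stage_select()].
#' @param config A [model_config()].
#' @return Numeric subjects-by-(1 or 2) matrix of summary scores.
#' @export
summarize_features <- function(features, selection, config) {
  features <- as_feature_matrix(features)
  if (nrow(selection) != ncol(features)) {
    abort("`selection` rows must match feature columns.")
  }
  w <- if (config$weighting == "r_weighted") selection$r else
    rep(1, nrow(selection))
  sum_over <- function(mask) {
    if (!any(mask)) return(rep(0, nrow(features)))
    as.numeric(features[, mask, drop = FALSE] %*% w[mask])
  }
  masks <- switch(config$selection_mode,
    positive = list(sum_pos = selection$selected_pos),
    negative = list(sum_neg = selection$selected_neg),
    both = list(sum_pos = selection$selected_pos,
                sum_neg = selection$selected_neg),
    dp = {
      dp_mask <- dp_select(config$dp_p, config$dp_alpha)
      if (length(dp_mask) != ncol(features)) {
        abort("`dp_p` length must match the feature count.")
      }
      list(sum_dp = dp_mask)
    })
  empty <- !vapply(masks, any, logical(1))
  if (any(empty)) {
    warn(paste0("Empty feature selection for: ",
                paste(names(masks)[empty], collapse = ", "),
                "; the corresponding summary is all zeros."))
  }
  out <- vapply(masks, sum_over, numeric(nrow(features)))
  matrix(out, nrow = nrow(features),
         dimnames = list(rownames(features), names(masks)))
}

#' Fit the second-stage regression
#'
#' Regresses the outcome on the per-subject feature sums, handling
#' covariates according to the configured scheme (see
#' [model_config()]).  Under the nuisance scheme, the outcome and the
#' sums are each residualized on the covariates (coefficients
#' estimated on these training data and stored for later test-set
#' residualization) and the model is fitted on the residuals; by the
#' Frisch--Waugh--Lovell theorem the sum coefficients agree with the
#' predictors scheme when fitted and evaluated in-sample.
#'
#' @param summaries Subjects-by-p summary matrix from
#'   [summarize_features()].
#' @param outcome Numeric outcome vector.
#' @param covariates Numeric covariate matrix (or `NULL`).
#' @param config A [model_config()].
#' @param selection The training `cpm_selection`, stored for prediction.
#' @return An object of class `cpm_fit`.
#' @export
fit_second_stage <- function(summaries, outcome, covariates = NULL,
                             config, selection = NULL) {
  summaries <- as.matrix(summaries)
  n <- nrow(summaries)
  y <- as.numeric(outcome)
  if (length(y) != n) abort("`outcome` length must match subjects.")
  has_cov <- !is.null(covariates) && NCOL(covariates) > 0L
  z <- if (has_cov) as.matrix(covariates) else NULL
  # all-zero summaries (empty selection) drop out of the design
  keep <- matrixStats_sd(summaries) > 0
  fallback <- !any(keep)
  s <- summaries[, keep, drop = FALSE]

  ols <- function(x, yv) {
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
      abort(paste0("Second-stage design is rank deficient; ",
                   "offending columns: ", paste(bad, collapse = ", ")))
    }
    setNames(as.numeric(qr.coef(qx, yv)), colnames(x))
  }
  icol <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))

  nuisance <- NULL
  if (config$covariate_role == "nuisance" && has_cov) {
    zd <- cbind(icol, z)
    gamma_y <- ols(zd, y)
    gamma_s <- if (ncol(s)) apply(s, 2, function(col) ols(zd, col)) else
      matrix(numeric(), ncol(zd), 0)
    gamma_s <- matrix(gamma_s, nrow = ncol(zd),
                      dimnames = list(colnames(zd), colnames(s)))
    nuisance <- list(gamma_y = gamma_y, gamma_s = gamma_s)
    y_res <- y - as.numeric(zd %*% gamma_y)
    s_res <- s - zd %*% gamma_s
    coefs <- ols(cbind(icol, s_res), y_res)
  } else if (config$covariate_role == "predictors" && has_cov) {
    coefs <- ols(cbind(icol, s, z), y)
  } else {
    coefs <- ols(cbind(icol, s), y)
  }
  structure(
    list(coefficients = coefs, nuisance = nuisance,
         summary_cols = colnames(summaries), kept_cols = keep,
         selection = selection, config = config,
         covariate_names = if (has_cov) colnames(z) else character(),
         fallback = fallback, n_train = n),
    class = "cpm_fit")
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat(sprintf("<cpm_fit> %s model, n = %d%s\n",
              x$config$selection_mode, x$n_train,
              if (x$fallback) " (covariate-only fallback)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @describeIn fit_second_stage Coefficients of a fitted second-stage
#'   model as a tibble (`term`, `estimate`).
#' @param x A `cpm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cpm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' Predict outcomes from a fitted second-stage model
#'
#' Computes feature sums on the test set with the training-set masks
#' and weights, then applies the fitted regression.  Under the nuisance
#' scheme the test sums are residualized first, using nuisance
#' coefficients from the training set (`nuisance_source = "train"`, the
#' only possibility when the test set is a single held-out subject) or
#' re-estimated from the test set itself (`"test"`, appropriate for
#' external validation where covariate shift is a concern); the
#' nuisance-predicted outcome component is then added back so
#' predictions are on the original outcome scale.
#'
#' @param object A `cpm_fit`.
#' @param features Test subjects-by-features matrix (same feature space
#'   as training).
#' @param phenotypes Test phenotype tibble (supplies covariates, and
#'   the observed outcome when `nuisance_source = "test"`).
#' @param nuisance_source `"train"` or `"test"`.
#' @param ... Unused.
#' @return Numeric vector of predicted outcomes.
#' @export
predict.cpm_fit <- function(object, features, phenotypes = NULL,
                            nuisance_source = c("train", "test"), ...) {
  nuisance_source <- match.arg(nuisance_source)
  features <- as_feature_matrix(features)
  if (!is.null(object$selection) &&
      nrow(object$selection) != ncol(features)) {
    abort(sprintf("Feature count mismatch: model has %d, data has %d.",
                  nrow(object$selection), ncol(features)))
  }
  n <- nrow(features)
  s_all <- withCallingHandlers(
    summarize_features(features, object$selection, object$config),
    warning = function(w) invokeRestart("muffleWarning"))
  s <- s_all[, object$kept_cols, drop = FALSE]
  z <- build_covariates(phenotypes, object$config$covariates)
  b <- object$coefficients
  icol <- matrix(1, n, 1)

  if (is.null(object$nuisance)) {
    x <- cbind(icol, s)
    if (object$config$covariate_role == "predictors") x <- cbind(x, z)
    return(as.numeric(x %*% b))
  }
  # nuisance scheme
  zd <- cbind(icol, z)
  if (nuisance_source == "train") {
    gamma_y <- object$nuisance$gamma_y
    gamma_s <- object$nuisance$gamma_s
  } else {
    if (n < max(2L, ncol(zd) + 1L)) {
      abort(paste0("Too few test subjects to estimate nuisance effects ",
                   "from the test set; use nuisance_source = \"train\"."))
    }
    y_test <- outcome_from(phenotypes, object$config)
    qz <- qr(zd)
    gamma_y <- as.numeric(qr.coef(qz, y_test))
    gamma_s <- matrix(qr.coef(qz, s), nrow = ncol(zd))
  }
  s_res <- s - zd %*% gamma_s
  y_res_hat <- as.numeric(cbind(icol, s_res) %*% b)
  y_res_hat + as.numeric(zd %*% gamma_y)   # add nuisance effects back
}

#' Leave-one-out cross-validated prediction
#'
#' Runs the full two-stage pipeline in a leave-one-out loop: for every
#' subject, features are selected and the model fitted on the remaining
#' subjects, and the held-out subject's outcome is predicted (nuisance
#' coefficients, where used, come from the training fold).  Per-fold
#' selection masks are retained for [feature_frequency()] maps.
#'
#' @param features Numeric subjects-by-features matrix.
#' @param phenotypes Phenotype tibble (one row per subject, same order).
#' @param config A [model_config()].
#' @return An object of class `cpm_cv`: predictions tibble
#'   (`subject_id`, `fold`, `observed`, `predicted`, `fallback`),
#'   per-fold positive/negative mask matrices, and the config.
#' @export
cpm_loocv <- function(features, phenotypes, config = model_config()) {
  features <- as_feature_matrix(features)
  n <- nrow(features)
  if (n != nrow(phenotypes)) abort("Feature and phenotype rows differ.")
  if (n < 3L) abort("Leave-one-out cross-validation needs >= 3 subjects.")
  if (n < 10L) warn(sprintf("Small sample (n = %d): results unstable.", n))
  y <- outcome_from(phenotypes, config)
  ids <- phenotypes$subject_id %||% rownames(features) %||%
    sprintf("sub%03d", seq_len(n))
  m <- ncol(features)
  mask_pos <- matrix(FALSE, n, m,
                     dimnames = list(ids, colnames(features)))
  mask_neg <- mask_pos
  predicted <- numeric(n)
  fallback <- logical(n)

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    cov_tr <- build_covariates(phenotypes[tr, , drop = FALSE],
                               config$covariates)
    sel <- first_stage_select(features[tr, , drop = FALSE], y[tr],
                              covariates = cov_tr,
                              alpha_select = config$alpha_select)
    fit <- withCallingHandlers(
      {
        summ <- summarize_features(features[tr, , drop = FALSE], sel,
                                   config)
        fit_second_stage(summ, y[tr], cov_tr, config, selection = sel)
      },
      warning = function(w) {
        if (grepl("Empty feature selection", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    predicted[i] <- predict(fit, features[i, , drop = FALSE],
                            phenotypes[i, , drop = FALSE],
                            nuisance_source = "train")
    fallback[i] <- fit$fallback
    mask_pos[i, ] <- sel$selected_pos
    mask_neg[i, ] <- sel$selected_neg
  }
  if (any(fallback)) {
    warn(sprintf("%d fold(s) had an empty feature selection and used %s.",
                 sum(fallback),
                 if (config$covariate_role == "none") "an intercept-only model"
                 else "a covariate-only model"))
  }
  structure(
    list(predictions = tibble::tibble(
           subject_id = ids, fold = seq_len(n), observed = y,
           predicted = predicted, fallback = fallback),
         masks = list(positive = mask_pos, negative = mask_neg),
         config = config, kind = "loocv",
         feature_ids = colnames(features)),
    class = "cpm_cv")
}

#' External validation on an independent cohort
#'
#' Fits the two-stage model once on the full training cohort and
#' predicts every subject of an independent test cohort.  Under the
#' nuisance scheme, nuisance effects are by default re-estimated from
#' the test set itself (`nuisance_source = "test"`).
#'
#' @param train_features,train_phenotypes Training cohort.
#' @param test_features,test_phenotypes Test cohort (identical feature
#'   space).
#' @param config A [model_config()].
#' @param nuisance_source Passed to [predict.cpm_fit()].
#' @return A `cpm_cv` object with `kind = "external"` (no fold masks:
#'   a single training-set selection is stored instead).
#' @export
cpm_external <- function(train_features, train_phenotypes,
                         test_features, test_phenotypes,
                         config = model_config(),
                         nuisance_source = "test") {
  train_features <- as_feature_matrix(train_features, "train_features")
  test_features <- as_feature_matrix(test_features, "test_features")
  if (ncol(train_features) != ncol(test_features)) {
    abort(sprintf("Feature count mismatch: train %d vs test %d.",
                  ncol(train_features), ncol(test_features)))
  }
  y_tr <- outcome_from(train_phenotypes, config)
  cov_tr <- build_covariates(train_phenotypes, config$covariates)
  sel <- first_stage_select(train_features, y_tr, covariates = cov_tr,
                            alpha_select = config$alpha_select)
  summ <- summarize_features(train_features, sel, config)
  fit <- fit_second_stage(summ, y_tr, cov_tr, config, selection = sel)
  predicted <- predict(fit, test_features, test_phenotypes,
                       nuisance_source = nuisance_source)
  y_te <- outcome_from(test_phenotypes, config)
  ids <- test_phenotypes$subject_id %||%
    sprintf("sub%03d", seq_len(nrow(test_features)))
  structure(
    list(predictions = tibble::tibble(
           subject_id = ids, fold = NA_integer_, observed = y_te,
           predicted = predicted, fallback = fit$fallback),
         masks = NULL, selection = sel, fit = fit,
         config = config, kind = "external",
         feature_ids = colnames(train_features)),
    class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf("<cpm_cv> %s, n = %d (%s model)\n", x$kind,
              nrow(x$predictions), x$config$selection_mode))
  p <- x$predictions
  cat(sprintf("  MAE = %.3f, r = %.3f, R2 = %.3f\n",
              mae(p$observed, p$predicted),
              tryCatch(pearson_r(p$observed, p$predicted),
                       error = function(e) NA_real_),
              cv_r2(p$observed, p$predicted)))
  invisible(x)
}

#' @describeIn cpm_loocv Per-subject observed/predicted pairs as a
#'   tibble.
#' @param x A `cpm_cv`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cpm_cv <- function(x, ...) x$predictions

#' Features selected in a high fraction of cross-validation folds
#'
#' Summarizes the stored per-fold selection masks of a leave-one-out
#' run: for each feature and association sign, the fraction of folds in
#' which it was selected.  Features recurring in at least `min_frac` of
#' folds (e.g. 50%) make up the consensus map of predictive edges or
#' vertices.
#'
#' @param result A `cpm_cv` from [cpm_loocv()].
#' @param min_frac Minimum selection fraction to report (default 0.5).
#' @param feature_meta Optional feature metadata tibble (keyed by
#'   `feature_id`) joined onto the result.
#' @return Tibble with columns `feature_id`, `sign`, `fraction` (plus
#'   metadata), sorted by decreasing fraction.
#' @export
feature_frequency <- function(result, min_frac = 0.5,
                              feature_meta = NULL) {
  if (!inherits(result, "cpm_cv") || is.null(result$masks)) {
    abort("`result` must be a LOOCV result with stored fold masks.")
  }
  frac <- function(mask, sign) {
    f <- colMeans(mask)
    tibble::tibble(feature_id = colnames(mask) %||%
                     sprintf("f%05d", seq_along(f)),
                   sign = sign, fraction = as.numeric(f))
  }
  out <- dplyr::bind_rows(frac(result$masks$positive, "positive"),
                          frac(result$masks$negative, "negative"))
  out <- dplyr::arrange(dplyr::filter(out, .data$fraction >= min_frac),
                        dplyr::desc(.data$fraction))
  if (!is.null(feature_meta)) {
    out <- dplyr::left_join(out, feature_meta, by = "feature_id")
  }
  out
}

#' Permutation test for a motion-outcome association
#'
#' Checks that in-scanner motion is not itself predictive of the
#' outcome: the observed Pearson correlation between per-subject mean
#' framewise displacement and the outcome is compared against its
#' permutation distribution under random relabeling.  For small samples
#' the full permutation set is enumerated; otherwise a seeded Monte
#' Carlo sample of `n_perm` permutations is used, with the two-tailed
#' p-value \eqn{(1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (n_{perm} + 1)}.
#'
#' @param fd_mean Per-subject mean framewise displacement.
#' @param outcome Per-subject outcome.
#' @param n_perm Number of Monte Carlo permutations (default 10000).
#' @param exact Enumerate all `n!` permutations; default when `n <= 7`.
#' @param seed Optional seed for the Monte Carlo draw.
#' @return One-row tibble: `r`, `p_value`, `n`, `n_perm`, `method`.
#' @export
motion_check <- function(fd_mean, outcome, n_perm = 10000,
                         exact = NULL, seed = NULL) {
  n <- length(fd_mean)
  if (n < 5L) abort("Need at least 5 subjects.")
  if (length(outcome) != n) abort("Input lengths differ.")
  if (sd(fd_mean) == 0 || sd(outcome) == 0) abort("Constant input.")
  exact <- exact %||% (n <= 7L)
  r_obs <- cor(fd_mean, outcome)
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(idx) cor(fd_mean, outcome[idx]))
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_used <- nrow(perms)
    method <- "exact"
  } else {
    r_perm <- local_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) cor(fd_mean, sample(outcome)), numeric(1))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
    method <- "monte_carlo"
  }
  tibble::tibble(r = r_obs, p_value = p, n = n, n_perm = n_used,
                 method = method)
}
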