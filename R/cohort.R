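#' Specify a synthetic two-session cohort
#'
#' Defines the generative model for a synthetic study: two sessions of
#' subject-by-feature brain data (connectome edges or vertexwise anatomy)
#' with a stable subject-specific "fingerprint" component plus session
#' noise, and a bounded integer clinical outcome driven by a sparse set of
#' signal features and by demographic covariates.
#'
#' Feature values follow
#' \deqn{x_{ise} = \mu_e + \sigma_{subj}\, u_{ie} + \sigma_{sess}\,
#'   \epsilon_{ise}}
#' where \eqn{\mu_e} is a fixed group profile, \eqn{u_{ie}} is drawn once
#' per subject and shared across sessions (this is what makes
#' fingerprint identification possible), and \eqn{\epsilon_{ise}} is
#' i.i.d. session noise.  The post-treatment outcome is a linear function
#' of the mean of the signal features at baseline, age, sex and the
#' baseline score, plus Gaussian noise, then rounded and clipped into
#' `outcome_range` so it behaves like a clinician-rated total score
#' (default 0--25, the range of the Pediatric Anxiety Rating Scale).
#'
#' Default values mimic a pediatric anxiety treatment cohort: ages
#' uniform on 8--17 years, sex Bernoulli(1/2) coded 0/1, baseline score
#' centred near 14.6 (SD 2.8) and follow-up mean near 9, and
#' framewise-displacement summaries centred near 0.12 mm.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of parcellation nodes; edge features are all
#'   `n_nodes * (n_nodes - 1) / 2` unique node pairs.  Ignored when
#'   `n_vertices` is given.
#' @param n_vertices If non-`NULL`, generate vertexwise anatomical
#'   features instead of edges (one feature per vertex).
#' @param n_timepoints Timecourse length for [generate_timecourses()].
#' @param sigma_subject Scale of the stable subject component.
#' @param sigma_session Scale of the session noise.
#' @param signal_feature_count Number of features linearly related to the
#'   outcome.
#' @param beta_signal Outcome effect per unit of the mean baseline value
#'   of the signal features.
#' @param beta_age,beta_sex,beta_baseline Covariate effects on the
#'   post-treatment outcome.
#' @param intercept Outcome intercept.
#' @param sigma_outcome SD of the outcome noise.
#' @param outcome_range Integer pair `c(min, max)`; the outcome is
#'   rounded and clipped into this range.
#' @param seed Integer seed; the same spec and seed always reproduce the
#'   identical cohort.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_timecourses()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 20, n_nodes = 10, seed = 1)
#' cohort <- generate_cohort(spec)
#' cohort$phenotypes
cohort_spec <- function(n_subjects = 60,
                        n_nodes = 30,
                        n_vertices = NULL,
                        n_timepoints = 150,
                        sigma_subject = 1,
                        sigma_session = 0.5,
                        signal_feature_count = 20,
                        beta_signal = 2,
                        beta_age = 0.1,
                        beta_sex = 0.5,
                        beta_baseline = 0.4,
                        intercept = 2,
                        sigma_outcome = 3,
                        outcome_range = c(0L, 25L),
                        seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 2L)
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 3L)
  assert_scalar_number(sigma_subject, "sigma_subject", min = 0)
  assert_scalar_number(sigma_session, "sigma_session", min = 0)
  assert_scalar_number(sigma_outcome, "sigma_outcome", min = 0)
  for (nm in c("beta_signal", "beta_age", "beta_sex", "beta_baseline",
               "intercept")) {
    assert_scalar_number(get(nm), nm)
  }
  seed <- assert_count(seed, "seed")
  if (!is.null(n_vertices)) {
    n_vertices <- assert_count(n_vertices, "n_vertices", min = 1L)
    n_features <- n_vertices
    feature_kind <- "vertex"
    n_nodes <- NULL
  } else {
    n_nodes <- assert_count(n_nodes, "n_nodes", min = 3L)
    n_features <- (n_nodes * (n_nodes - 1L)) %/% 2L
    feature_kind <- "edge"
  }
  signal_feature_count <- assert_count(signal_feature_count,
                                       "signal_feature_count", min = 0L)
  if (signal_feature_count > n_features) {
    abort(sprintf(
      "`signal_feature_count` (%d) exceeds the number of features (%d).",
      signal_feature_count, n_features))
  }
  if (length(outcome_range) != 2L || !is.numeric(outcome_range) ||
      outcome_range[1] >= outcome_range[2]) {
    abort("`outcome_range` must be an increasing pair c(min, max).")
  }
  structure(
    list(n_subjects = n_subjects, n_nodes = n_nodes,
         n_vertices = n_vertices, n_features = n_features,
         feature_kind = feature_kind, n_timepoints = n_timepoints,
         sigma_subject = sigma_subject, sigma_session = sigma_session,
         signal_feature_count = signal_feature_count,
         beta_signal = beta_signal, beta_age = beta_age,
         beta_sex = beta_sex, beta_baseline = beta_baseline,
         intercept = intercept, sigma_outcome = sigma_outcome,
         outcome_range = as.integer(round(outcome_range)), seed = seed),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects, %d %s features (%d signal), seed %d\n",
    x$n_subjects, x$n_features, x$feature_kind,
    x$signal_feature_count, x$seed))
  cat(sprintf("  sigma_subject = %g, sigma_session = %g, sigma_outcome = %g\n",
              x$sigma_subject, x$sigma_session, x$sigma_outcome))
  invisible(x)
}

# Feature metadata for the spec's parcellation: edge endpoints with
# network assignments, or vertex ids.
feature_meta_for_spec <- function(spec) {
  if (spec$feature_kind == "vertex") {
    return(tibble::tibble(
      feature_id = sprintf("v%05d", seq_len(spec$n_features)),
      vertex_id = seq_len(spec$n_features)))
  }
  n <- spec$n_nodes
  networks <- paste0("net", rep_len(1:17, n))
  labels <- sprintf("node%03d", seq_len(n))
  idx <- upper_pairs(n)
  tibble::tibble(
    feature_id = sprintf("e%05d", seq_len(nrow(idx))),
    node_a = labels[idx[, 1]], node_b = labels[idx[, 2]],
    network_a = networks[idx[, 1]], network_b = networks[idx[, 2]])
}

# Row-major strict upper-triangle index pairs of an n x n matrix.
upper_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  a <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  b <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  cbind(a, b)
}

#' Generate a synthetic two-session cohort
#'
#' Draws the cohort defined by a [cohort_spec()]: two subject-by-feature
#' matrices (baseline and follow-up sessions, shared subject and feature
#' order), a phenotype table, and the generative truth (signal-feature
#' indices and all coefficients) for parameter-recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `baseline`, `followup` (numeric subject x feature matrices),
#'   `feature_meta` (tibble), `phenotypes` (tibble with columns
#'   `subject_id`, `outcome_baseline`, `outcome_post`, `age`, `sex`,
#'   `scanner`, `fd_mean`, `fd_pct_above`), and `truth`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  n <- spec$n_subjects
  m <- spec$n_features
  local_seed(spec$seed, {
    ids <- sprintf("sub%03d", seq_len(n))
    mu <- rnorm(m)                       # group profile, drawn once
    u <- matrix(rnorm(n * m), n, m)      # subject fingerprint component
    baseline <- sweep(spec$sigma_subject * u +
                        spec$sigma_session * matrix(rnorm(n * m), n, m),
                      2, mu, "+")
    followup <- sweep(spec$sigma_subject * u +
                        spec$sigma_session * matrix(rnorm(n * m), n, m),
                      2, mu, "+")
    meta <- feature_meta_for_spec(spec)
    dimnames(baseline) <- dimnames(followup) <- list(ids, meta$feature_id)

    lo <- spec$outcome_range[1]; hi <- spec$outcome_range[2]
    age <- runif(n, 8, 17)
    sex <- rbinom(n, 1L, 0.5)
    scanner <- sample(c("scanner1", "scanner2"), n, replace = TRUE)
    fd_mean <- abs(rnorm(n, 0.12, 0.05))
    fd_pct_above <- pmin(100, 100 * fd_mean * abs(rnorm(n, 0.8, 0.3)))
    outcome_baseline <- pmin(hi, pmax(lo, round(rnorm(n, 14.6, 2.8))))

    signal_idx <- if (spec$signal_feature_count > 0) {
      sort(sample.int(m, spec$signal_feature_count))
    } else integer()
    signal_term <- if (length(signal_idx)) {
      rowMeans(baseline[, signal_idx, drop = FALSE])
    } else rep(0, n)
    latent <- spec$intercept + spec$beta_signal * signal_term +
      spec$beta_age * age + spec$beta_sex * sex +
      spec$beta_baseline * outcome_baseline +
      rnorm(n, 0, spec$sigma_outcome)
    outcome_post <- as.integer(pmin(hi, pmax(lo, round(latent))))

    phenotypes <- tibble::tibble(
      subject_id = ids,
      outcome_baseline = as.integer(outcome_baseline),
      outcome_post = outcome_post,
      age = age, sex = sex, scanner = scanner,
      fd_mean = fd_mean, fd_pct_above = fd_pct_above)

    structure(
      list(baseline = baseline, followup = followup,
           feature_meta = meta, phenotypes = phenotypes,
           truth = list(
             signal_features = meta$feature_id[signal_idx],
             signal_idx = signal_idx,
             group_profile = mu,
             coefficients = spec[c("intercept", "beta_signal", "beta_age",
                                   "beta_sex", "beta_baseline")],
             spec = spec)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects x %d %s features, 2 sessions\n",
    nrow(x$baseline), ncol(x$baseline), x$truth$spec$feature_kind))
  cat(sprintf("  %d signal features; seed %d\n",
              length(x$truth$signal_idx), x$truth$spec$seed))
  invisible(x)
}

#' Generate node timecourses under a latent-factor model
#'
#' Simulates per-subject, per-session node timecourse arrays whose
#' population correlation structure contains a subject-specific
#' component: each subject carries a stable loading matrix
#' \eqn{\Lambda_i = \Lambda_0 + \sigma_{subj}\Delta_i}, perturbed per
#' session by \eqn{\sigma_{sess}\,\Xi_{is}}, and the observed array is
#' \eqn{Y = F\Lambda_{is}^\top + E} with i.i.d. standard-normal factor
#' scores \eqn{F} and unit observation noise \eqn{E}.
#'
#' @param spec A [cohort_spec()] (uses `n_nodes`, `n_timepoints`,
#'   `sigma_subject`, `sigma_session`, `seed`).
#' @param loadings Optional fixed nodes-by-factors loading matrix used
#'   for every subject and session (overrides the random loadings);
#'   useful for controlled simulations.
#' @param n_factors Number of latent factors when `loadings` is random.
#' @return A tibble with columns `subject_id`, `session` (`"baseline"` /
#'   `"followup"`) and `tc`, a list-column of timepoints-by-nodes
#'   matrices with node-label column names.
#' @export
generate_timecourses <- function(spec, loadings = NULL, n_factors = 3L) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  if (spec$feature_kind != "edge") {
    abort("Timecourse simulation requires a node-based (edge) spec.")
  }
  v <- spec$n_nodes
  t_len <- spec$n_timepoints
  if (t_len < 3L || v < 2L) abort("Degenerate dimensions for timecourses.")
  if (!is.null(loadings)) {
    loadings <- as.matrix(loadings)
    if (nrow(loadings) != v) {
      abort(sprintf("`loadings` must have %d rows (one per node).", v))
    }
    n_factors <- ncol(loadings)
  }
  node_labels <- sprintf("node%03d", seq_len(v))
  local_seed(spec$seed, {
    lambda0 <- loadings %||% matrix(rnorm(v * n_factors), v, n_factors)
    out <- vector("list", 2L * spec$n_subjects)
    row <- 0L
    ids <- sprintf("sub%03d", seq_len(spec$n_subjects))
    for (i in seq_len(spec$n_subjects)) {
      delta <- if (is.null(loadings)) {
        spec$sigma_subject * matrix(rnorm(v * n_factors), v, n_factors)
      } else 0
      for (s in c("baseline", "followup")) {
        xi <- if (is.null(loadings)) {
          spec$sigma_session * matrix(rnorm(v * n_factors), v, n_factors)
        } else 0
        lam <- lambda0 + delta + xi
        f <- matrix(rnorm(t_len * n_factors), t_len, n_factors)
        y <- f %*% t(lam) + matrix(rnorm(t_len * v), t_len, v)
        colnames(y) <- node_labels
        row <- row + 1L
        out[[row]] <- tibble::tibble(subject_id = ids[i], session = s,
                                     tc = list(y))
      }
    }
    dplyr::bind_rows(out)
  })
}
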