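# Cohort file I/O, run manifests, report tables and cohort comparison.

write_tsv_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "subject_id")
  readr::write_tsv(df, path)
}

read_tsv_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_feature_matrix(as.data.frame(df))
}

run_manifest <- function(command, config, seeds, inputs = character(),
                         extra = list()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  c(list(command = command,
         package = "connpredict",
         version = as.character(utils::packageVersion("connpredict")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seeds = seeds, config = config, input_digests = digests),
    extra)
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Write and read a synthetic cohort as delimited text
#'
#' Serializes a [generate_cohort()] result to plain-text files in a
#' directory: `baseline_features.tsv` and `followup_features.tsv`
#' (subjects in rows, a `subject_id` column plus one column per
#' feature), `phenotypes.csv`, `feature_meta.tsv`, `truth.json`
#' (generative ground truth), and a `manifest.json` recording the spec,
#' seed and file digests.  `read_cohort()` restores the object.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort("`cohort` must come from generate_cohort().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(cohort$baseline, file.path(dir, "baseline_features.tsv"))
  write_tsv_matrix(cohort$followup, file.path(dir, "followup_features.tsv"))
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  readr::write_tsv(cohort$feature_meta, file.path(dir, "feature_meta.tsv"))
  truth <- cohort$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- file.path(dir, c("baseline_features.tsv",
                            "followup_features.tsv", "phenotypes.csv",
                            "feature_meta.tsv", "truth.json"))
  write_manifest(run_manifest("simulate", unclass(truth$spec),
                              seeds = truth$spec$seed, inputs = files),
                 dir)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("baseline_features.tsv",
                           "followup_features.tsv", "phenotypes.csv",
                           "truth.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(paste0("Missing cohort files: ",
                 paste(basename(missing), collapse = ", ")))
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  args <- truth$spec[intersect(names(truth$spec),
                               names(formals(cohort_spec)))]
  args <- args[lengths(args) > 0L]   # JSON nulls read back as empty
  spec <- do.call(cohort_spec, args)
  truth$spec <- spec
  meta_path <- file.path(dir, "feature_meta.tsv")
  structure(
    list(baseline = read_tsv_matrix(need[1]),
         followup = read_tsv_matrix(need[2]),
         feature_meta = if (file.exists(meta_path)) {
           readr::read_tsv(meta_path, show_col_types = FALSE)
         } else NULL,
         phenotypes = readr::read_csv(need[3], show_col_types = FALSE),
         truth = truth),
    class = "synthetic_cohort")
}

#' Format and parse report cells like "3.4735[3.1024-3.8543]"
#'
#' Metric tables report each quantity as `point[lo-hi]` with four
#' decimals and negative numbers parenthesized, e.g.
#' `0.0757[(-0.1449)-0.2700]`.  `parse_metric_cell()` recovers the
#' three numbers from such a cell.
#'
#' @param point,lo,hi Numbers to format.
#' @param cell A formatted cell string.
#' @return `format_metric_cell()`: a string; `parse_metric_cell()`: a
#'   named numeric vector `c(point, lo, hi)`.
#' @export
format_metric_cell <- function(point, lo, hi) {
  f <- function(x) {
    s <- sprintf("%.4f", x)
    if (x < 0) paste0("(", s, ")") else s
  }
  sprintf("%s[%s-%s]", f(point), f(lo), f(hi))
}

#' @rdname format_metric_cell
#' @export
parse_metric_cell <- function(cell) {
  # negatives are always parenthesized, so a bare "-" only separates
  # the two interval bounds
  toks <- regmatches(
    cell, gregexpr("\\(-?[0-9]+\\.[0-9]+\\)|[0-9]+\\.[0-9]+", cell))[[1]]
  vals <- as.numeric(gsub("[()]", "", toks))
  if (length(vals) != 3L) abort("Not a metric cell: point[lo-hi].")
  setNames(vals, c("point", "lo", "hi"))
}

#' Render a metrics report as a publication-style table row
#'
#' Produces the one-row layout used for model-comparison tables:
#' predictor set, nuisance set, then MAE, r and R^2 each with its
#' bracketed 95% interval.
#'
#' @param metrics A `metrics_report` (from [prediction_metrics()] /
#'   [glance.cpm_cv()]).
#' @param predictors,nuisance Label strings for the first two columns.
#' @return One-row tibble with character columns `Predictors`,
#'   `Nuisance`, `MAE`, `r`, `R2`.
#' @export
render_metrics_row <- function(metrics, predictors = "Positive edges",
                               nuisance = "None") {
  tibble::tibble(
    Predictors = predictors, Nuisance = nuisance,
    MAE = format_metric_cell(metrics$mae, metrics$mae_lo, metrics$mae_hi),
    r = format_metric_cell(metrics$r, metrics$r_lo, metrics$r_hi),
    R2 = format_metric_cell(metrics$r2, metrics$r2_lo, metrics$r2_hi))
}

#' Run the predictive pipeline and write a report
#'
#' End-to-end driver: applies the motion quality-control rule
#' ([qc_exclude()]) to the phenotype table, drops and records excluded
#' subjects, runs leave-one-out cross-validation (or external
#' validation when a test cohort is supplied), and writes
#' `metrics.json`, `metrics.csv` (rendered table row), a frequent-
#' feature TSV (LOOCV only) and a run manifest into `output_dir`.
#'
#' @param features,phenotypes Training cohort.
#' @param config A [model_config()].
#' @param output_dir Output directory.
#' @param test_features,test_phenotypes Optional external-validation
#'   cohort; when given, mode is external.
#' @param feature_meta Optional feature metadata for the frequency
#'   table.
#' @param n_boot,seed Bootstrap settings for the metric intervals.
#' @param min_frac Threshold for [feature_frequency()].
#' @return The `metrics_report` tibble, invisibly.
#' @export
run_prediction_report <- function(features, phenotypes,
                                  config = model_config(),
                                  output_dir,
                                  test_features = NULL,
                                  test_phenotypes = NULL,
                                  feature_meta = NULL,
                                  n_boot = 1000, seed = 1L,
                                  min_frac = 0.5) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  features <- as_feature_matrix(features)

  drop_qc <- function(feat, phen) {
    excl <- qc_exclude(phen$fd_mean, phen$fd_pct_above)
    list(features = feat[!excl, , drop = FALSE],
         phenotypes = phen[!excl, , drop = FALSE],
         excluded = phen$subject_id[excl])
  }
  tr <- drop_qc(features, phenotypes)
  external <- !is.null(test_features)
  if (external) {
    te <- drop_qc(as_feature_matrix(test_features), test_phenotypes)
    cv <- cpm_external(tr$features, tr$phenotypes, te$features,
                       te$phenotypes, config)
    excluded <- list(train = tr$excluded, test = te$excluded)
  } else {
    cv <- cpm_loocv(tr$features, tr$phenotypes, config)
    excluded <- list(train = tr$excluded)
  }
  metrics <- prediction_metrics(cv, n_boot = n_boot, seed = seed)
  jsonlite::write_json(as.list(metrics),
                       file.path(output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  pred_label <- paste(c(sprintf("%s edges", tools::toTitleCase(
                          config$selection_mode)),
                        if (config$covariate_role == "predictors")
                          config$covariates),
                      collapse = ", ")
  nuis_label <- if (config$covariate_role == "nuisance") {
    paste(config$covariates, collapse = ", ")
  } else "None"
  readr::write_csv(render_metrics_row(metrics, pred_label, nuis_label),
                   file.path(output_dir, "metrics.csv"))
  if (!external) {
    freq <- feature_frequency(cv, min_frac = min_frac,
                              feature_meta = feature_meta)
    readr::write_tsv(freq, file.path(output_dir, "frequent_features.tsv"))
  }
  write_manifest(run_manifest(
    if (external) "predict-external" else "predict-loocv",
    unclass(config)[setdiff(names(config), "dp_p")],
    seeds = seed,
    extra = list(qc_excluded = excluded,
                 n_analyzed = nrow(tr$features))), output_dir)
  invisible(metrics)
}

#' Run the fingerprinting analysis and write a report
#'
#' Runs [fingerprint()] on two-session feature matrices after motion
#' QC, and writes `identification.json` (counts, accuracies, binomial
#' p-values), `dp_table.tsv` (per-feature differential power) and a
#' manifest into `output_dir`.
#'
#' @param baseline,followup Subjects-by-features matrices.
#' @param phenotypes Optional phenotype table for QC exclusion.
#' @param output_dir Output directory.
#' @param feature_meta Optional metadata joined onto the DP table.
#' @return The `fingerprint_result`, invisibly.
#' @export
run_fingerprint_report <- function(baseline, followup,
                                   phenotypes = NULL, output_dir,
                                   feature_meta = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  baseline <- as_feature_matrix(baseline, "baseline")
  followup <- as_feature_matrix(followup, "followup")
  excluded <- character()
  if (!is.null(phenotypes)) {
    excl <- qc_exclude(phenotypes$fd_mean, phenotypes$fd_pct_above)
    excluded <- phenotypes$subject_id[excl]
    baseline <- baseline[!excl, , drop = FALSE]
    followup <- followup[!excl, , drop = FALSE]
  }
  fp <- fingerprint(baseline, followup)
  jsonlite::write_json(as.list(glance(fp)),
                       file.path(output_dir, "identification.json"),
                       auto_unbox = TRUE, digits = NA)
  dp_tbl <- fp$dp
  if (!is.null(feature_meta)) {
    dp_tbl <- dplyr::left_join(dp_tbl, feature_meta, by = "feature_id")
  }
  readr::write_tsv(dp_tbl, file.path(output_dir, "dp_table.tsv"))
  write_manifest(run_manifest("fingerprint", list(), seeds = NULL,
                              extra = list(qc_excluded = excluded,
                                           n_analyzed = nrow(baseline))),
                 output_dir)
  invisible(fp)
}

#' Compare two cohorts variable by variable
#'
#' Produces a descriptives-and-tests table in the style of a clinical
#' Table 1: for each continuous variable a two-sample pooled-variance
#' t-test (Welch optional), and for each binary variable a 2x2
#' chi-squared test with Yates continuity correction.  Full-precision
#' statistics are returned; `statistic_rounded` / `p_rounded` carry the
#' two-decimal rendering used in printed tables.
#'
#' @param table_a,table_b Phenotype tibbles for the two groups.
#' @param continuous Names of continuous variables present in both.
#' @param binary Names of binary (0/1 or two-level) variables.
#' @param pooled Use the pooled-variance t-test (default); `FALSE`
#'   gives Welch.
#' @return Tibble: `variable`, `type`, `mean_a`, `sd_a` (or counts),
#'   `mean_b`, `sd_b`, `statistic`, `p_value`, `statistic_rounded`,
#'   `p_rounded`.
#' @export
cohort_compare <- function(table_a, table_b,
                           continuous = c("age", "outcome_baseline",
                                          "outcome_post", "fd_mean",
                                          "fd_pct_above"),
                           binary = "sex",
                           pooled = TRUE) {
  if (nrow(table_a) == 0L || nrow(table_b) == 0L) {
    abort("Both tables must be nonempty.")
  }
  rows <- list()
  for (v in continuous) {
    a <- table_a[[v]]; b <- table_b[[v]]
    tt <- t.test(a, b, var.equal = pooled)
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
      statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  for (v in binary) {
    a <- factor(table_a[[v]]); b <- factor(table_b[[v]])
    lev <- union(levels(a), levels(b))
    if (length(lev) < 2L) {
      abort(sprintf("Variable `%s` has a single category.", v))
    }
    if (length(lev) != 2L) {
      abort(sprintf("Variable `%s` is not binary.", v))
    }
    tab <- rbind(table(factor(a, lev)), table(factor(b, lev)))
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    rows[[v]] <- tibble::tibble(
      variable = v, type = "binary",
      mean_a = mean(a == lev[2]), sd_a = NA_real_,
      mean_b = mean(b == lev[2]), sd_b = NA_real_,
      statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  out <- dplyr::bind_rows(rows)
  out$statistic_rounded <- round(out$statistic, 2)
  out$p_rounded <- round(out$p_value, 2)
  out
}
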