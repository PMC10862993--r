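Package: connpredict
Title: Connectome and Anatomical Predictive Modeling with Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome Predictive Modeling (CPM) and its anatomical
    analogue (APM) for predicting clinical outcomes from brain features:
    first-stage feature selection by correlation with the outcome,
    network-summary second-stage regression with four nuisance-handling
    schemes, leave-one-out and external validation, and prediction metrics
    (MAE, r, cross-validated R-squared) with bootstrap confidence
    intervals.  Also implements functional-connectome fingerprinting:
    subject identification across sessions with a binomial null, the
    edgewise decomposition of cross-session correlations, per-edge
    match-probability estimates, and the differential-power statistic with
    chi-squared inference, usable as an alternative feature-selection
    criterion.  A synthetic two-session cohort generator provides data
    with the statistical structure the methods assume, so the full
    pipeline can be exercised and validated without access to clinical
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    MASS,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
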