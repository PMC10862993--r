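---
title: "Predictive modeling and fingerprinting of brain features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive modeling and fingerprinting of brain features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(connpredict)
```

# The problem

Given a cohort of subjects with brain features — resting-state
functional-connectivity edges (Fisher-z correlations between
parcellated node timecourses) or vertexwise anatomical measurements —
and a bounded clinical score (for instance a clinician-rated anxiety
total on a 0–25 scale), two questions recur:

1. **Prediction.** Can the features predict the score of an unseen
   subject, and how should demographic covariates enter the model?
2. **Uniqueness.** How identifiable are individual subjects across
   scanning sessions, which features carry that identity, and do those
   "fingerprint" features overlap with the predictive ones?

`connpredict` implements both analyses end to end, together with a
synthetic two-session cohort generator so that every stage can be
validated without clinical imaging data.

# The predictive model

The model is the standard two-stage summed-feature regression (CPM
when the features are connectome edges, APM when they are vertexwise
anatomy; the machinery is identical and the package makes no
distinction beyond feature metadata).

**Stage 1 — selection** (`first_stage_select()`). Every feature is
correlated with the outcome across training subjects.  Without
covariates this is the Pearson correlation with the two-sided
parametric p-value from \(t = r\sqrt{df}/\sqrt{1-r^2}\), \(df = n-2\);
with covariates it is the partial correlation given the covariates
(\(df = n-2-k\)), equivalent to the t-test on the feature coefficient
in a joint regression.  Features with \(p < \alpha\) (default
\(\alpha = 0.01\)) are retained, split by association sign.  The
positive and negative masks are disjoint by construction.

**Stage 2 — summary and regression** (`summarize_features()`,
`fit_second_stage()`). Each subject's selected feature values are
summed — one sum for `positive` or `negative` mode, two separate sum
predictors for `both` (a design choice: keeping the two sets as
separate regressors preserves the interpretability of each
coefficient; a difference score would force a common slope).  The
outcome is regressed on the sums by ordinary least squares.  An
optional `r_weighted` variant multiplies each feature by its
training-set correlation before summing; it is provided as an option
(default off) since "unweighted sums" are the reference behaviour.

**Covariate schemes.** Age, sex, scanner (dummy-coded) and the
baseline score may enter three ways:

* `none` — sums only;
* `predictors` — covariates are ordinary second-stage regressors;
* `nuisance` — outcome and sums are residualized on the covariates
  (coefficients estimated on the training set), the model is fitted on
  residuals, and at prediction time the test data are residualized
  with coefficients from the training set (`nuisance_source =
  "train"`, the only possibility when the test fold is a single
  subject) or re-estimated on the test set (`"test"`, preferable for
  external validation when the test cohort is large enough for the
  covariate distribution to have drifted).  The nuisance-predicted
  component is always added back to the predictions, so reported
  errors live on the original outcome scale.

By the Frisch–Waugh–Lovell theorem the `predictors` and `nuisance`
schemes produce identical in-sample predictions; the test suite
asserts this to \(10^{-8}\).  They genuinely differ out of sample,
which is the point of the distinction.

**Validation.** `cpm_loocv()` repeats selection, summarization and
fitting inside a leave-one-out loop, predicting each held-out subject
with training-fold nuisance coefficients, and stores each fold's
selection masks; `feature_frequency()` turns these into consensus maps
(features selected in at least, say, 50% of folds).
`cpm_external()` fits once on a training cohort and predicts an
independent cohort.  Folds whose selection is empty fall back to a
covariate-only (or intercept-only) model and are flagged — a
deliberate choice over failing, since empty selections are routine in
weak-signal clinical data.  LOOCV runs for any \(n \ge 3\) but warns
below \(n = 10\); at very small \(n\) the training folds cannot
support selection and every fold uses the fallback.

**Metrics** (`prediction_metrics()`). Prediction quality is judged by
the mean absolute error, the Pearson correlation \(r\) between
observed and predicted values, and the cross-validation form of the
coefficient of determination
\[
R^2 \;=\; 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\]
which is *not* \(r^2\) and is negative whenever the predictions do
worse than the observed mean.  \(\bar y\) is taken as the mean of the
observed outcomes of the evaluated set (all pooled leave-one-out
predictions, or the external test set); this choice is isolated in
`cv_r2()` so an alternative convention would be a one-line change.
Confidence intervals are percentile bootstrap over resampled
(observed, predicted) pairs — the model is not refitted per replicate
— with 1000 replicates by default.  Replicates whose resampled
observed vector is constant (leaving \(r\) and \(R^2\) undefined) are
redrawn, up to 100 attempts, rather than dropped, keeping the
replicate count fixed; redraw counts are reported.

**Motion.** `qc_exclude()` implements the scan-exclusion rule: mean
framewise displacement above 0.25 mm, or more than 50% of frames
individually above 0.25 mm.  Both thresholds are strict inequalities
("greater than"), so a scan exactly at a boundary is kept.
`motion_check()` guards against motion artifacts masquerading as
signal: a permutation test of the correlation between mean FD and the
outcome, exhaustive for \(n \le 7\) and seeded Monte Carlo (default
10,000 draws, p-value \((1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n_{perm}+1)\))
otherwise.

# Fingerprinting

`fingerprint()` matches each subject's baseline feature vector to the
most similar follow-up vector by Pearson correlation (and the
reverse), with replacement.  Under chance matching each identification
succeeds with probability \(1/n\), so the number of correct matches is
Binomial\((n, 1/n)\); `binomial_identification_p()` evaluates the
upper tail in log space, which matters because real identification
counts produce p-values far below double-precision underflow when
exponentiated naively.

The per-feature machinery rests on the observation that a Pearson
correlation is the dot product of mean-centred, unit-norm vectors, so
it decomposes additively over features:
\(r_{ij} = \sum_e \varphi_{ij}(e)\) with
\(\varphi_{ij}(e) = \tilde x_i^b(e)\,\tilde x_j^f(e)\)
(`phi_contributions()`; the decomposition is exact and the test suite
asserts it to \(10^{-10}\)).  For subject \(i\) and feature \(e\), the
estimated probability that the self-match contribution is matched or
beaten by chance is
\[
\hat P_i(e) = \frac{\sum_j I(\varphi_{ij}(e) \ge \varphi_{ii}(e)) +
\sum_j I(\varphi_{ji}(e) \ge \varphi_{ii}(e)) - 1}{2n - 1},
\]
implemented literally (`p_hat_matrix()`): both indicator sums include
\(j = i\), each contributing 1, and the \(-1\) offsets exactly one of
them, bounding the estimate in \([1/(2n-1),\,1]\).  The
differential power of a feature is \(DP(e) = -2\sum_i \ln \hat
P_i(e)\), tested against a \(\chi^2\) distribution with \(2n\) degrees
of freedom (`differential_power()`), and `dp_select()` thresholds the
resulting p-values to produce an alternative feature-selection mask
for the predictive model (`model_config(selection_mode = "dp")`).

**A calibration caveat, verified by simulation.**  The \(\chi^2(2n)\)
null is exact when the per-subject match probabilities are uniformly
distributed on \((0, 1]\) — the package's tests confirm uniform
p-values (Kolmogorov–Smirnov) in that regime.  The plug-in estimator
\(\hat P_i(e)\), however, is discrete (a grid of \(2n-1\) values, so
\(-2\ln\hat P\) is bounded above) and its per-subject terms are
dependent within a feature (they share the same rank structure).  On
genuinely null two-session data the empirical \(DP\) therefore sits
*below* its nominal \(\chi^2(2n)\) reference and the p-values are
conservative (stochastically large) — the package asserts this
direction rather than pretending uniformity holds.  DP-based selection
consequently errs on the side of selecting too little under the null,
which is the safe direction for a screening statistic.

The full \(\varphi\) tensor is \(n^2 \times M\); `p_hat_matrix()`
streams over features in blocks (default 512) so memory stays bounded,
and the result is independent of the block size (asserted in tests).
Argmax ties in identification are broken toward the lowest subject
index with a warning; for continuous data they have probability zero.

# The synthetic cohort generator

`generate_cohort()` draws the minimal data-generating process the
analyses assume:

\[
x_{ise} = \mu_e + \sigma_{subj}\,u_{ie} + \sigma_{sess}\,\epsilon_{ise},
\]

with a group feature profile \(\mu_e \sim N(0,1)\) drawn once per
cohort, a subject component \(u_{ie}\) drawn once per subject and
shared across the two sessions (this is what makes fingerprinting
possible), and i.i.d. session noise.  The post-treatment outcome is

\[
y_i = \beta_0 + \beta_{sig}\,\overline{x^{sig}_i} + \beta_{age}\,a_i +
\beta_{sex}\,s_i + \beta_{base}\,y^0_i + \varepsilon_i,
\]

rounded and clipped to the declared range (default 0–25, mimicking a
clinician-rated anxiety total), where \(\overline{x^{sig}_i}\) is the
subject's mean over a sparse random set of signal features at
baseline.  Demographics mirror a pediatric cohort: age uniform on
8–17 years, sex Bernoulli(1/2), baseline severity centred near 14.6
(SD 2.8), follow-up mean near 9, and framewise-displacement summaries
centred near 0.12 mm — values chosen once to resemble published
descriptive statistics for such samples, and not revisited.
`generate_timecourses()` provides the upstream latent-factor
simulation of node timecourses for exercising the connectivity
functions.

Two structural consequences are worth knowing when interpreting test
results.  First, because the signal features are i.i.d., each one's
correlation with the outcome is capped near \(1/\sqrt{K}\) for \(K\)
signal features; strong-recovery regimes therefore use sparse signals
(the package's validation uses \(K = 4\)–5 of 105 features).  Second,
rounding and clipping are genuine noise: even a noiseless linear
signal cannot reach \(r = 1\) after integer rounding.

**What the generator does not emulate:** BOLD autocorrelation and
hemodynamics, motion artifacts in the images themselves, scanner or
site effects on features, spatial correlation among edges or vertices,
and cortical geometry.  Passing tests on synthetic cohorts validate
the *statistical machinery* — selection, cross-validation hygiene,
nuisance handling, calibration of the null distributions — not the
claim that real connectomes predict real clinical outcomes.

# Connectivity features

`compute_rsfc()` produces full (pairwise Pearson) or partial
connectivity.  Partial correlations are computed through the
(pseudo-)inverse of the sample covariance,
\(\rho_{ab} = -P_{ab}/\sqrt{P_{aa}P_{bb}}\), which is mathematically
identical to correlating each pair's residuals after regressing out
all remaining nodes but costs one matrix inversion instead of
\(O(N^2)\) regressions; the test suite cross-checks the two routes to
\(10^{-8}\).  Correlations are clipped to \(\pm(1-10^{-12})\) before
\(z = \mathrm{arctanh}(r)\), so duplicated timecourses yield a large
finite \(z\) instead of infinity.  `vectorize_upper()` fixes the edge
order as the row-major strict upper triangle — (1,2), (1,3), …,
(1,N), (2,3), … — so a 216-node parcellation yields 23,220 edge
features; either triangle carries the same information and this
convention is simply frozen.

`smooth_on_mesh()` approximates Gaussian surface smoothing by
iterated neighbor averaging with the iteration count calibrated via
the diffusion approximation \(FWHM \approx L\sqrt{8\ln(2)\,k/3}\) for
mean edge length \(L\), i.e. \(k = \lceil 3(FWHM/L)^2/(8\ln 2)\rceil\).
This is an approximation adequate for feature smoothing, not a
geometric heat-kernel solver; the global mean is preserved exactly by
re-centering, and isolated vertices are left untouched with a warning.

# Numerical and design choices

* **Empty selection** falls back to a covariate-only (or
  intercept-only) second stage with a logged flag, never an error.
* **Change-score outcome** is defined as post − baseline, so negative
  values mean improvement.
* **The binomial tail** is implemented as \(P(X \ge k_{obs})\); this
  reading reproduces analytic reference values to two significant
  figures (see `scripts/acceptance.R`), which pins down the otherwise
  ambiguous "location" convention.
* **Cohort comparison** (`cohort_compare()`) defaults to the
  pooled-variance two-sample t-test for continuous variables and the
  Yates-corrected \(\chi^2\) for 2×2 tables — the conventions that
  reproduce standard printed clinical-table statistics from their
  counts; Welch is available by flag.
* **Degenerate bootstrap replicates** are redrawn, not dropped.
* **Determinism**: every stochastic routine accepts a seed and
  restores the caller's RNG state; identical seeds give byte-identical
  serialized outputs.

# Problem sizes used in validation

The shipped test-suite simulations use cohorts of 15–120 subjects on
10–21-node parcellations (45–210 edges), 20–200 replicate cohorts for
calibration properties, and 200–1000 bootstrap replicates — sizes
chosen so the complete statistical argument (null calibration,
parameter recovery, scheme equivalences) runs comfortably on a
laptop.  All of the machinery scales unchanged to real dimensions
(tens of thousands of features); `p_hat_matrix()` and `cpm_loocv()`
stream over features and folds respectively.

# Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 60, n_nodes = 15,
                    signal_feature_count = 5, beta_signal = 8,
                    sigma_outcome = 0.5, seed = 1)
cohort <- generate_cohort(spec)

cfg <- model_config(selection_mode = "both",
                    covariate_role = "nuisance",
                    covariates = c("age", "sex", "outcome_baseline"))
cv <- cpm_loocv(cohort$baseline, cohort$phenotypes, cfg)
glance(cv, n_boot = 1000, seed = 1)
autoplot(cv)

fp <- fingerprint(cohort$baseline, cohort$followup)
glance(fp)
plot_differential_power(fp)
```

# Limitations

* The second stage is ordinary least squares only; regularized or
  nonlinear variants are out of scope, as are k-fold schemes other
  than leave-one-out.
* The DP formulation here is the reformulated estimator with the
  \([1/(2n-1), 1]\) bounds and \(\chi^2(2n)\) aggregation; the
  original exceedance-count formulation is not provided.
* Surface smoothing is a mesh-graph approximation; no image or
  surface file I/O is included — features arrive as matrices or
  delimited text.
* Site/scanner harmonization beyond a dummy-coded covariate is not
  addressed.
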