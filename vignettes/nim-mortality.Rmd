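---
title: "The NIM index mortality pipeline: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NIM index mortality pipeline: models, generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimsurv)
```

# The scientific question

The cholinergic anti-inflammatory pathway lets efferent vagal activity
inhibit cytokine release; its functionality should therefore show up as
the *joint* configuration of high vagally-mediated heart rate variability
(vmHRV) and low circulating inflammation. The neuroimmunomodulation (NIM)
index condenses this into one number per person from RMSSD (the root mean
square of successive interbeat-interval differences, in ms) and an
inflammatory marker (CRP in µg/ml or IL-6 in pg/ml), and the pipeline
asks whether people in the lowest quartile of the index die sooner than
those in the highest, across two heterogeneous population cohorts.

# Index construction

Within each dataset, RMSSD and the marker are z-transformed (sample sd,
denominator n−1), so each person is located relative to their own
cohort; `zscore_by_stratum()` enforces non-degenerate strata. The two
standardized components are then combined by `nim_score()`:

* **difference** (default): `z_rmssd − z_marker`. Monotone increasing in
  vagal tone and decreasing in inflammation everywhere, defined for every
  record.
* **ratio**: `z_rmssd / z_marker`, the literal quotient. Because the
  denominator is a mean-zero z-score, the quotient diverges and loses
  monotonicity near zero; records with `|z_marker| < 0.05` are therefore
  flagged and excluded from quartiling rather than propagated.

The difference is the default because every downstream step consumes
only quartile membership, for which the difference is the well-behaved
monotone analogue; published per-quartile index values in this literature
(means near 1 with narrow ranges) cannot arise from a raw ratio of
mean-zero z-scores, so the exact published transform is not recoverable
and no attempt is made to reproduce those numeric ranges. Both methods
are kept so the literal definition remains available.

Z-transforms operate on the raw measurements by default, as the
definition states; `log_markers = TRUE` standardizes natural-log values
instead, which is more robust for the right-skewed markers but is an
option, not the default.

Quartiles are assigned on the scores pooled across datasets — the
dataset-wise standardization is precisely what makes pooling meaningful,
and near-balanced per-dataset quartile counts follow automatically.
Cutpoints are the linear-interpolation (type 7) 25th/50th/75th
percentiles; a value equal to a cutpoint goes to the lower group, a
deterministic and documented tie rule. Per-dataset quartiling is
available via `pool_quartiles = FALSE`.

# Survival analysis

`cox_fit()` maximizes the stratified Cox partial likelihood from scratch:
each dataset-by-sex stratum keeps its own unspecified baseline hazard and
contributes its own log partial likelihood. Numerical choices:

* Newton–Raphson from β = 0 with step-halving; convergence when the
  relative change in log partial likelihood is below 1e−9, at most 100
  iterations; standard errors from the inverse observed information.
* Ties: Efron by default — the more accurate approximation — with Breslow
  available for bit-faithful emulation of software whose default it is.
  The analysis this pipeline mirrors was run in a commercial package that
  does not state its tie rule; on tie-free (continuous) simulated times
  the two coincide exactly, and the test suite checks both against an
  independent reference implementation to 1e−6.
* A coefficient escaping |β| > 20 is treated as monotone likelihood
  (separation) and flagged as non-convergence; a rank-deficient design or
  singular information matrix is an error naming the covariates.
* Age and BMI are centered at pooled means before fitting. This affects
  only the implicit baseline, never coefficients or standard errors (a
  tested invariance), but matches how the adjusted effects are reported
  ("per year above the average age").

`model_report()` moves to the hazard-ratio scale: HR = exp(β), delta-rule
standard error HR·se, normal-approximation 95% CI with multiplier 1.96
(matching the reporting convention of the reference analysis), and
percent-change phrasing 100·(HR−1). AIC = −2ℓ + 2k; BIC = −2ℓ + k·ln(n)
with n = subjects by default — the convention of the software the
reference analysis used — and n = events as an option, since survival
folklore differs on this point.

`km_curve()` is the product-limit estimator with deaths processed before
censorings at tied times; `logrank_test()` aggregates observed minus
hypergeometric-expected events over distinct death times with the
hypergeometric covariance, dropping one group and using a generalized
inverse only if the reduced covariance is singular.

`two_stage_meta()` implements the two-stage individual-participant-data
view: sex-stratified Cox fits within each dataset, then fixed-effect
inverse-variance pooling of the quartile-4-vs-1 log hazard ratio, with
Cochran's Q and I² = max(0, (Q−df)/Q)·100. Fixed-effect (not
random-effects) pooling is deliberate: with two studies a between-study
variance estimate is unstable, and the reference analysis reports only Q
and I² with one degree of freedom. The one-stage stratified fit remains
the headline estimate; the two-stage pool quantifies cohort
heterogeneity.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not any individual-level feature of the real cohorts:

* **Marginals** (`cohort_spec`, defaults in `default_cohort_specs()`):
  two cohorts of 922 and 2,938 participants. RMSSD, CRP and IL-6 are
  log-normal, moment-matched to the published arithmetic mean/sd
  (σ² = ln(1+s²/m²), µ = ln(m²/√(m²+s²))) — the simplest family
  consistent with positivity and the strong right skew (sd ≈ mean in the
  descriptive tables). Age and BMI are normal, truncated at physiological
  bounds (18 years, 14 kg/m²). Sex and ethnicity are independent
  Bernoulli draws.
* **Coupling** (`coupling_spec`): a Gaussian copula imposes Spearman
  correlations (converted to latent Pearson via r = 2 sin(πρ/6)).
  Defaults — age↔log RMSSD −0.25, age↔log marker +0.15, BMI↔log marker
  +0.20, BMI↔log RMSSD −0.10, log RMSSD↔log marker −0.20 — take their
  signs from the physiological literature (vmHRV falls and inflammation
  rises with age and adiposity; vmHRV and inflammation are inversely
  related); their magnitudes are assumptions, since the source analyses
  publish no covariate correlation matrix. The CRP↔IL-6 rank correlation
  (0.40) and a zero age↔BMI correlation are likewise package choices on
  axes the published material does not constrain.
* **Mortality** (`survival_spec`): exponential baseline per
  dataset-by-sex stratum with the female baseline at 0.6× the male one
  (the analysis stratifies by sex but publishes no sex-specific rates; a
  fixed plausible ratio keeps strata non-degenerate), times
  exp(linear predictor) with the quartile, age, BMI and ethnicity effects
  set to the published adjusted estimates: quartile hazard ratios
  (1, .619, .427, .547) for the IL-6 model and (1, .603, .583, .566) for
  CRP; age +10.7%/year (IL-6 model) and +11.1%/year (CRP); BMI
  +2.5%/unit; ethnicity null. Quartile membership used for hazard
  assignment is computed by the index module on the generated biomarkers,
  so index construction and mortality are coupled exactly as in the
  analysis. Censoring is purely administrative — 177 months minus a
  60-month uniform entry window, and 216 minus 24 — reproducing the two
  median follow-ups to first order; no dropout process is simulated
  because none is described.

## Calibration

The adjusted quartile hazard ratio (0.55) is narrower than the published
*unadjusted* 18-year survival gap (75% vs 91%), which implies confounding
between age and the index. The calibration (`calibrate_generator()`)
therefore searches two knobs by coordinate bisection: a shared multiplier
on all baseline rates (targets the overall death fraction, 11.1%,
tolerance 1 point) and `age_coupling_scale`, a multiplier on the two age
correlations (targets the 216-month survival in the lowest and highest
quartile, tolerance 2 points each). Each candidate is scored on one
fixed-seed simulated study with cohort sizes scaled ×5 (`eval_scale`):
at the natural study size the Monte-Carlo error of the death fraction
(≈0.5 points) and of a quartile survival fraction (≈1.4 points) is
comparable to those tolerances, so the evaluation study is enlarged —
the marginal quantities being matched do not depend on the study size.
The search stops as soon as all three targets are inside tolerance, or
errors after 50 evaluations reporting the best point found.

The shipped defaults (`calibration_defaults()`) are the frozen output of
this procedure: multiplier 1.0905 with scale 1.0 for the IL-6 model, and
1.0 / 1.0 for the CRP model (whose targets, 79%/91%, the uncalibrated
defaults already meet). They are data, reproducible by re-running the
calibration, not tuning parameters.

## What passing tests do and do not show

The generator reproduces marginal moments, rank correlations, the
proportional-hazards effect structure, administrative censoring, and the
calibrated marginal survival quantities. It does **not** reproduce:
measurement error or day-to-day biological variability in RMSSD and the
markers beyond their cross-sectional spread; loss to follow-up or
competing risks; enrollment calendars; the selection process that reduced
the source cohorts to complete cases; or any non-proportional hazards.
Parameter recovery on this analogue therefore validates the pipeline's
statistics — that the estimator finds the truth when the model is true —
not the epidemiological conclusions of any particular cohort.

# Problem sizes and runtime choices

Validation runs use 100 replicate studies of 3,860 records per marker
(the acceptance script and the end-to-end test file share this design),
large-sample checks use 50,000–200,000 draws (200,000 for the log-normal
sd recovery of CRP, whose σ ≈ 1.07 makes the sample sd itself noisy to
≈2% at 50,000), and the Monte-Carlo oracle for the moment-matching
formula uses 10⁶ draws. Small-instance Cox oracles use n ≤ 8 with a
grid-search maximizer of the brute-force partial likelihood.

# Known limitations

* The ratio method's ε-guard (0.05) is a pragmatic cut; near-threshold
  records are excluded, not winsorized.
* The artifact filter in `rmssd()` (running-median, 25% deviation,
  disabled by default) is a screen for gross ectopy in synthetic or
  well-edited series, not a substitute for proper tachogram editing.
* With two cohorts, I² from the two-stage pool is highly variable; the
  homogeneity check uses its median across replicates.
* The per-dataset baseline rates (5.7e−4 and 9.4e−4 per month for men,
  before calibration) were set from the published crude death fractions
  and follow-up durations after accounting for the cohorts' age
  structures; they are generator conditions, not estimates.
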