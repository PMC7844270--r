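# nimsurv

Survival analysis of a composite **vagal neuroimmunomodulation (NIM)
index** — standardized vagally-mediated heart rate variability (RMSSD)
set against a standardized circulating inflammatory marker (CRP or
IL-6) — as a predictor of all-cause mortality in general-population
cohorts. The index proxies the functionality of the cholinergic
anti-inflammatory pathway: high vagal tone together with low inflammation
scores high; low vagal tone with high inflammation scores low.

The package is aimed at biostatisticians and psychophysiologists who want
to (a) compute the index and its quartile risk groups from participant
tables or raw interbeat-interval series, (b) estimate its association with
mortality, and (c) validate the whole pipeline end-to-end on a calibrated
two-cohort synthetic analogue with known generating effects.

## What it computes

For participant *i* in dataset *d* with RMSSD \(r_i\) and marker \(m_i\):

- dataset-stratified z-scores \(z^r_i = (r_i - \bar r_d)/s^r_d\),
  \(z^m_i = (m_i - \bar m_d)/s^m_d\);
- NIM score \(z^r_i - z^m_i\) (default; the literal quotient
  \(z^r_i / z^m_i\) is available with a guard against near-zero
  denominators), quartiled on the pooled scores;
- a Cox proportional-hazards model on follow-up time with quartile
  indicators (quartile 1 = reference), age and BMI centered at the pooled
  means, and non-white ethnicity, with a separate baseline hazard per
  dataset-by-sex stratum:
  \(\lambda_i(t) = \lambda_{0s}(t)\exp(\beta_2 Q2_i + \beta_3 Q3_i +
  \beta_4 Q4_i + \beta_a \,\text{age}_i + \beta_b \,\text{BMI}_i +
  \beta_e \,\text{eth}_i)\),
  maximized by Newton-Raphson on the stratified partial likelihood
  (Efron or Breslow ties), with AIC/BIC reporting;
- Kaplan-Meier curves per quartile and the k-sample log-rank test;
- a two-stage individual-participant-data meta-analysis: per-dataset
  sex-stratified fits pooled by fixed-effect inverse variance, with
  Cochran's Q and I² heterogeneity statistics.

The survival machinery (Kaplan-Meier, log-rank, stratified Cox) is
implemented in the package itself; the `survival` package is used only as
an independent cross-check in the test suite.

A synthetic-data module generates two-cohort studies (n = 922 + 2,938)
with Gaussian-copula-coupled log-normal biomarkers, truncated-normal age
and BMI, and an exponential-baseline proportional-hazards mortality
process under administrative censoring, calibrated so the marginal death
fraction (11.1%) and the 216-month quartile survival fractions match the
reference analysis while the generating hazard ratios stay at the
reported adjusted estimates.

## Worked example

```r
library(nimsurv)
study <- generate_study(1, marker = "IL6")   # calibrated synthetic study
an <- run_analysis(study, marker = "IL6")
print(an)
```

```
NIM mortality analysis [marker IL6, method difference]
  n = 3860, deaths = 443

Stratified Cox proportional-hazards fit (efron ties)
  n = 3860, events = 443, loglik = -2998.5012, iterations = 4

      term     hr   se_hr       z         p  ci_lo  ci_hi
 quartile2 0.4873 0.05959 -5.8785 4.139e-09 0.3835 0.6193
 quartile3 0.3912 0.05413 -6.7826 1.180e-11 0.2983 0.5131
 quartile4 0.4198 0.06492 -5.6129 1.989e-08 0.3100 0.5684
       age 1.0925 0.00774 12.4878 8.699e-36 1.0774 1.1078
       bmi 1.0280 0.01142  2.4834 1.301e-02 1.0058 1.0506
  nonwhite 1.1588 0.18319  0.9322 3.512e-01 0.8500 1.5797

AIC = 6009.002, BIC = 6046.553
Log-rank test: chi2(3) = 158.95, p = <2e-16
Fixed-effect meta-analysis (2 studies)
  pooled beta = -0.869 (HR 0.4194), se = 0.1569
  Cochran's Q = 2.266 (df 1, p = 0.132), I2 = 55.9%
KM survival at 216 months by quartile: Q1 75.1%, Q2 88.2%, Q3 92.0%, Q4 93.4%
```

Reading the output: participants in the highest index quartile have an
adjusted hazard ratio of 0.42 against the lowest quartile in this single
replicate (i.e. 58% lower instantaneous death risk; the generating value
is 0.547 and single-study estimates scatter around it), each year of age
raises the death risk by 9.3%, and 75.1% of the lowest quartile versus
93.4% of the highest survive to 18 years (216 months). Averaging over 100
replicates (`replicate_study("IL6", 100, seed = 1)`) recovers the
generating quantities; single replicates wobble around them.

RMSSD from raw interbeat intervals:

```r
seg <- system.file("extdata", "ibi_synthetic_seg1.txt", package = "nimsurv")
rmssd(read_ibi(seg))       # 28.9 ms for this synthetic segment
average_segments(c(28.9, 23.8))  # two-segment protocol -> 26.35 ms
```

A thin command-line front end with subcommands `simulate`, `hrv`,
`index`, `fit`, `meta`, `replicate` lives at
`inst/cli/nimsurv.R` (`Rscript <path>/nimsurv.R simulate --seed 1 --out study.csv`).

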