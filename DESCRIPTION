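Package: nimsurv
Title: Vagal Neuroimmunomodulation Index and All-Cause Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs a composite vagal neuroimmunomodulation (NIM) index
    from vagally-mediated heart rate variability (RMSSD) and circulating
    inflammatory markers (CRP or IL-6), assigns quartile risk groups, and
    estimates the association of the index with all-cause mortality using
    stratified Cox proportional-hazards models, Kaplan-Meier curves,
    k-sample log-rank tests, and two-stage individual-participant-data
    meta-analysis with Cochran's Q and I-squared. Includes a calibrated
    two-cohort survival simulator for end-to-end validation of the
    pipeline, with Gaussian-copula coupled log-normal biomarkers and a
    proportional-hazards mortality process under administrative censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
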