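test_that("log-normal moment matching reproduces the target moments", {
  # closed form: m = s gives sigma^2 = ln 2; checked against brute-force
  # Monte-Carlo moments of the matched log-normal at n = 1e6
  prm <- nimsurv:::lnorm_params(5, 5)
  expect_equal(prm$sigma^2, log(2))
  set.seed(2024)
  draw <- stats::rlnorm(1e6, prm$mu, prm$sigma)
  expect_lt(abs(mean(draw) - 5) / 5, 0.01)
  expect_lt(abs(stats::sd(draw) - 5) / 5, 0.02)
})

test_that("sampled marginals recover the cohort specification at large n", {
  co <- default_cohort_specs()$MIDUS
  # CRP's matched log-normal has sigma ~ 1.07, so the sample sd itself has
  # ~2% Monte Carlo error at n = 50k; 200k keeps the check sharp.
  co$n <- 200000L
  rec <- sample_biomarkers(co, coupling_spec(), seed = 123)
  expect_lt(abs(mean(rec$rmssd) - 10.7) / 10.7, 0.01)
  expect_lt(abs(stats::sd(rec$rmssd) - 8.43) / 8.43, 0.02)
  for (v in c("crp", "il6")) {
    m <- co[[paste0(v, "_mean")]]; s <- co[[paste0(v, "_sd")]]
    expect_lt(abs(mean(rec[[v]]) - m) / m, 0.02)
    expect_lt(abs(stats::sd(rec[[v]]) - s) / s, 0.02)
  }
  expect_true(all(rec$age >= 18))
  expect_true(all(rec$bmi >= 14))
  expect_lt(abs(mean(rec$sex == "female") - co$female_frac), 0.01)
})

test_that("the Gaussian copula realizes the requested rank correlations", {
  co <- default_cohort_specs()$Whitehall
  co$n <- 50000L
  coup <- coupling_spec()
  rec <- sample_biomarkers(co, coup, seed = 321)
  rho <- function(a, b) stats::cor(a, b, method = "spearman")
  expect_lt(abs(rho(rec$age, log(rec$rmssd)) - coup$rho_age_logrmssd), 0.03)
  expect_lt(abs(rho(rec$age, log(rec$il6)) - coup$rho_age_logmarker), 0.03)
  expect_lt(abs(rho(rec$bmi, log(rec$crp)) - coup$rho_bmi_logmarker), 0.03)
  expect_lt(abs(rho(log(rec$rmssd), log(rec$il6)) - coup$rho_logrmssd_logmarker), 0.03)
  expect_lt(abs(rho(log(rec$crp), log(rec$il6)) - coup$rho_markers), 0.03)
  # independence case: zero coupling leaves age and log IL-6 uncorrelated
  rec0 <- sample_biomarkers(co, coupling_spec(0, 0, 0, 0, 0, 0), seed = 11)
  expect_lt(abs(rho(rec0$age, log(rec0$il6))), 0.02)
})

test_that("a non-positive-definite coupling is rejected with the offending pair", {
  expect_error(coupling_spec(rho_age_logrmssd = 0.95, rho_age_logmarker = 0.95,
                             rho_logrmssd_logmarker = -0.95),
               "not positive definite")
  expect_error(coupling_spec(rho_age_logrmssd = 1.2), "\\(-1, 1\\)")
})

test_that("survival assignment honors null and exponential limits", {
  co <- cohort_spec("one", 2000, 60, 5, 25, 3, 20, 10, 2, 2, 2, 2,
                    female_frac = 0.5, nonwhite_frac = 0.1,
                    admin_censor_months = 1e5, entry_spread_months = 10)
  rec <- sample_biomarkers(co, coupling_spec(), seed = 1)
  null_spec <- survival_spec(c(0, 0, 0, 0), 0, 0, 0,
                             c("one:male" = 0, "one:female" = 0))
  out0 <- assign_survival(rec, rep(1L, 2000), null_spec, list(co), seed = 2)
  expect_true(all(out0$event == 0))
  expect_true(all(out0$time <= 1e5 & out0$time >= 1e5 - 10))
  # flat positive hazard, effectively no censoring: mean time ~ 1/rate
  lam <- 0.02
  flat <- survival_spec(c(0, 0, 0, 0), 0, 0, 0,
                        c("one:male" = lam, "one:female" = lam))
  out1 <- assign_survival(rec, rep(1L, 2000), flat, list(co), seed = 3)
  expect_gt(mean(out1$event), 0.99)
  expect_lt(abs(mean(out1$time) - 1 / lam) / (1 / lam), 0.05)
})

test_that("quartile log-hazards translate into event-rate ratios under rare events", {
  co <- cohort_spec("one", 40000, 60, 5, 25, 3, 20, 10, 2, 2, 2, 2,
                    0.5, 0.1, admin_censor_months = 100,
                    entry_spread_months = 0)
  rec <- sample_biomarkers(co, coupling_spec(), seed = 4)
  spec <- survival_spec(c(0, 0, 0, log(0.5)), 0, 0, 0,
                        c("one:male" = 2e-4, "one:female" = 2e-4))
  q <- rep(c(1L, 4L), length.out = 40000)
  out <- assign_survival(rec, q, spec, list(co), seed = 5)
  rate_q1 <- mean(out$event[q == 1]); rate_q4 <- mean(out$event[q == 4])
  expect_lt(abs(rate_q4 / rate_q1 - 0.5), 0.07)
  expect_error(assign_survival(rec, q, survival_spec(
    c(0, 0, 0, 0), 0, 0, 0, c("one:male" = 1e-4)), list(co), seed = 1),
    "one:female")
  expect_error(assign_survival(rec, rep(5L, 40000), spec, list(co), 1),
               "1..4")
})

test_that("study generation is deterministic and reproduces the study design", {
  s1 <- generate_study(42, marker = "IL6")
  s2 <- generate_study(42, marker = "IL6")
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 3860L)
  expect_equal(as.integer(table(s1$dataset)[c("MIDUS", "Whitehall")]),
               c(922L, 2938L))
  expect_false(identical(s1$time, generate_study(43, marker = "IL6")$time))
})

test_that("calibration returns immediately when targets are already met", {
  cal <- calibrate_generator(default_survival_spec("IL6"),
                             default_coupling_spec("IL6"), marker = "IL6")
  expect_true(cal$converged)
  expect_equal(nrow(cal$trace), 1L)
  expect_equal(cal$rate_multiplier, 1)
  expect_equal(cal$survival$baseline_rate,
               default_survival_spec("IL6")$baseline_rate)
})

test_that("infeasible calibration targets raise informative errors", {
  expect_error(calibrate_generator(
    default_survival_spec("IL6"), coupling_spec(),
    targets = list(overall_death_frac = 0, km18_q1 = 0.75, km18_q4 = 0.91)),
    "\\(0, 1\\)")
  expect_error(calibrate_generator(
    default_survival_spec("IL6"), coupling_spec(),
    targets = list(overall_death_frac = 5e-4, km18_q1 = 0.999,
                   km18_q4 = 0.9995),
    tol = c(death = 1e-4, km = 1e-4), eval_scale = 1L, max_iter = 8L),
    "did not converge")
})

test_that("study CSV and YAML round-trips preserve the data and specs", {
  study <- generate_study(9, marker = "CRP")
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(study, path, specs = list(cohorts = default_cohort_specs()))
  expect_match(readLines(path, n = 1), "seed: 9")
  back <- read_study(path)
  expect_equal(back$time, study$time, tolerance = 1e-12)
  expect_equal(back$event, study$event)
  expect_equal(back$id, study$id)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  specs <- list(cohorts = default_cohort_specs(),
                coupling = default_coupling_spec("IL6"),
                survival = default_survival_spec("IL6"))
  specs_to_yaml(specs, ypath)
  back_specs <- specs_from_yaml(ypath)
  expect_equal(back_specs$cohorts$MIDUS$n, 922L)
  expect_equal(back_specs$coupling$age_coupling_scale,
               specs$coupling$age_coupling_scale)
  expect_equal(back_specs$survival$beta_quartile, specs$survival$beta_quartile)
  expect_equal(back_specs$survival$baseline_rate, specs$survival$baseline_rate)
})
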