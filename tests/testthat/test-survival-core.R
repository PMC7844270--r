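test_that("Kaplan-Meier matches hand-computed product limits", {
  # no events: flat at 1
  k0 <- km_curve(c(3, 7, 9), c(0, 0, 0))
  expect_equal(km_survival(k0, c(0, 5, 100)), c(1, 1, 1))
  # {5 censored, 10 event, 15 event}: risk sets 2 then 1
  k1 <- km_curve(c(5, 10, 15), c(0, 1, 1))
  expect_equal(km_survival(k1, c(9.99, 10, 14.9, 15, 20)),
               c(1, 0.5, 0.5, 0, 0))
})

test_that("Kaplan-Meier equals 1 - ECDF without censoring and is monotone", {
  set.seed(21)
  tt <- sort(stats::rexp(40, 0.1)) + 0.01
  k <- km_curve(tt, rep(1, 40))
  expect_equal(km_survival(k, tt), 1 - stats::ecdf(tt)(tt))
  expect_equal(km_survival(k, max(tt)), 0)
  expect_true(all(diff(k$surv) <= 1e-15))
  expect_true(all(k$surv >= 0 & k$surv <= 1))
})

test_that("deaths precede censorings in tied risk sets", {
  # censored at 10 must still be at risk for the death at 10
  k <- km_curve(c(10, 10), c(1, 0))
  expect_equal(k$surv, 0.5)
  expect_equal(k$n_risk, 2)
})

test_that("log-rank is zero under identical groups and matches the termwise oracle", {
  tt <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 0, 1, 1, 0)
  lr0 <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$df, 1L)
  # tiny 2-group instance enumerated risk set by risk set
  time <- c(1, 2, 3, 4); event <- rep(1, 4); grp <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$chi2, brute_logrank_chi2(time, event, grp), tolerance = 1e-12)
  # and a larger randomized instance, 3 groups
  set.seed(5)
  tt <- stats::rexp(60, 0.1) + 0.1; ev <- stats::rbinom(60, 1, 0.6)
  g <- sample(c("x", "y", "z"), 60, TRUE)
  expect_equal(logrank_test(tt, ev, g)$chi2, brute_logrank_chi2(tt, ev, g),
               tolerance = 1e-10)
})

test_that("log-rank is invariant to group relabeling and needs 2 groups and an event", {
  set.seed(6)
  tt <- stats::rexp(50, 0.1) + 0.1; ev <- stats::rbinom(50, 1, 0.5)
  g <- sample(c("a", "b", "c"), 50, TRUE)
  relab <- c(a = "z3", b = "z1", c = "z2")[g]
  expect_equal(logrank_test(tt, ev, g)$chi2, logrank_test(tt, ev, relab)$chi2)
  expect_gte(logrank_test(tt, ev, g)$chi2, 0)
  expect_error(logrank_test(tt, ev, rep("a", 50)), "2 groups")
  expect_error(logrank_test(tt, rep(0, 50), g), "1 event")
})

test_that("Cox coefficient is ~0 for an exchangeable binary covariate", {
  # both arms show the same outcome pattern, so the labels carry no signal
  fit <- cox_fit(rep(c(1, 2, 3, 4), 2), rep(1, 8),
                 cbind(g = c(0, 1, 0, 1, 1, 0, 1, 0)))
  expect_lt(abs(fit$coef), 1e-8)
})

test_that("Newton estimates match grid-search maximization of the partial likelihood", {
  # 6-record instance with one tied death pair, Efron ties
  time <- c(1, 1, 2, 3, 4, 5)
  event <- c(1, 1, 1, 0, 1, 1)
  x <- c(0.5, 1, -0.3, 0, 1.2, -1)
  fit <- cox_fit(time, event, cbind(x = x), ties = "efron")
  expect_lt(abs(fit$coef - brute_cox_coef(time, event, x, "efron")), 1e-4)
  # randomized small instances, both tie rules
  set.seed(99)
  for (i in 1:20) {
    inst <- random_small_instance(8L)
    if (sum(inst$event) < 2) inst$event[1:2] <- 1L
    ties <- if (i %% 2 == 0) "efron" else "breslow"
    fit <- cox_fit(inst$time, inst$event, cbind(x = inst$x), ties = ties)
    if (!fit$converged || abs(fit$coef) > 4.5) next  # near-separated draw
    expect_lt(abs(fit$coef - brute_cox_coef(inst$time, inst$event, inst$x,
                                            ties)), 1e-3)
  }
})

test_that("Cox fit agrees with the reference implementation to 1e-6", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 250
  df <- data.frame(a = stats::rnorm(n), b = stats::rbinom(n, 1, 0.4),
                   st = sample(c("s1", "s2", "s3"), n, TRUE))
  df$time <- ceiling(stats::rexp(n, 0.08 * exp(0.6 * df$a - 0.4 * df$b)))
  df$event <- stats::rbinom(n, 1, 0.7)
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(df$time, df$event, cbind(a = df$a, b = df$b),
                   strata = df$st, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ a + b +
                             survival::strata(st), data = df, ties = ties)
    expect_lt(max(abs(fit$coef - stats::coef(ref))), 1e-6)
    expect_lt(max(abs(fit$se - sqrt(diag(stats::vcov(ref))))), 1e-6)
    expect_lt(abs(fit$loglik - ref$loglik[2]), 1e-6)
  }
})

test_that("score vanishes at the optimum and tie rules agree on tie-free data", {
  set.seed(15)
  n <- 150
  x <- cbind(a = stats::rnorm(n), b = stats::runif(n))
  tt <- stats::rexp(n, 0.1 * exp(0.4 * x[, 1]))  # continuous: no ties
  ev <- stats::rbinom(n, 1, 0.8)
  fe <- cox_fit(tt, ev, x, ties = "efron")
  fb <- cox_fit(tt, ev, x, ties = "breslow")
  expect_lt(max(abs(fe$score)), 1e-6)
  expect_equal(fe$coef, fb$coef)
  expect_equal(fe$loglik, fb$loglik)
})

test_that("estimates are invariant to covariate shifts and scale consistently", {
  set.seed(16)
  n <- 120
  age <- stats::rnorm(n, 55, 8)
  tt <- stats::rexp(n, 0.05 * exp(0.05 * (age - 55))); ev <- rep(1, n)
  f1 <- cox_fit(tt, ev, cbind(age = age), center = FALSE)
  f2 <- cox_fit(tt, ev, cbind(age = age - mean(age)), center = FALSE)
  f3 <- cox_fit(tt, ev, cbind(age = age), center = TRUE)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
  expect_equal(f1$se, f2$se, tolerance = 1e-9)
  expect_equal(f1$coef, f3$coef, tolerance = 1e-9)
  # affine recoding: coefficient scales by 1/c
  f4 <- cox_fit(tt, ev, cbind(age = age / 10))
  expect_equal(unname(f4$coef), unname(10 * f1$coef), tolerance = 1e-7)
})

test_that("separation is flagged and collinearity is an error", {
  # all deaths in one arm, before every censoring: monotone likelihood
  tt <- c(1, 2, 3, 10, 11, 12); ev <- c(1, 1, 1, 0, 0, 0)
  x <- cbind(bad = c(1, 1, 1, 0, 0, 0))
  fit <- suppressWarnings(cox_fit(tt, ev, x))
  expect_false(fit$converged)
  set.seed(17)
  z <- stats::rnorm(30)
  expect_error(cox_fit(stats::rexp(30) + 0.1, stats::rbinom(30, 1, 0.8),
                       cbind(a = z, b = 2 * z)), "collinear")
})

test_that("model report transforms to the hazard-ratio scale correctly", {
  fit <- structure(list(coef = c(x = 0, y = log(0.547)),
                        se = c(x = 0.1, y = 0.147), var = diag(2),
                        loglik = -100, loglik_null = -110, score = c(0, 0),
                        iter = 3L, converged = TRUE, n = 50, n_event = 20,
                        ties = "efron"), class = "nim_cox")
  rep <- model_report(fit)
  expect_equal(rep$hr[1], 1)
  expect_equal(rep$ci_lo[1], exp(-1.96 * 0.1))
  expect_equal(rep$ci_hi[1], exp(1.96 * 0.1))   # = 1.21653
  expect_equal(rep$pct_change[2], -45.3)
  expect_equal(rep$se_hr, rep$hr * fit$se, ignore_attr = TRUE)
  # AIC/BIC definitions: k = 2 covariates
  expect_equal(attr(rep, "AIC"), -2 * -100 + 4)
  expect_equal(attr(rep, "BIC"), 200 + 2 * log(50))
  expect_equal(attr(model_report(fit, bic_n = "events"), "BIC"),
               200 + 2 * log(20))
  fit$converged <- FALSE
  expect_warning(model_report(fit), "unconverged")
})
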