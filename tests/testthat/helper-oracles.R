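# Independent brute-force oracles, written from the defining formulas with
# explicit loops; they never call the package's own survival code paths.

# Log partial likelihood (Efron or Breslow ties) for a single stratum and a
# single covariate, evaluated termwise for a vector of beta values.
brute_partial_loglik <- function(beta, time, event, x,
                                 ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  vapply(beta, function(b) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      risk <- which(time >= t)
      deaths <- which(time == t & event == 1)
      d <- length(deaths)
      w <- exp(b * x)
      ll <- ll + sum(b * x[deaths])
      if (ties == "breslow" || d == 1L) {
        ll <- ll - d * log(sum(w[risk]))
      } else {
        for (l in seq_len(d) - 1L) {
          ll <- ll - log(sum(w[risk]) - (l / d) * sum(w[deaths]))
        }
      }
    }
    ll
  }, numeric(1))
}

# Maximize the brute-force partial likelihood by grid search on [-5, 5]
# with local refinement.
brute_cox_coef <- function(time, event, x, ties = "efron") {
  grid <- seq(-5, 5, by = 0.001)
  ll <- brute_partial_loglik(grid, time, event, x, ties = ties)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  fine[which.max(brute_partial_loglik(fine, time, event, x, ties = ties))]
}

# Termwise k-sample log-rank statistic from the defining O/E/V sums.
brute_logrank_chi2 <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    n <- sum(risk)
    d <- sum(time == t & event == 1)
    for (j in seq_len(k)) {
      nj <- sum(risk & group == levels(group)[j])
      O[j] <- O[j] + sum(time == t & event == 1 & group == levels(group)[j])
      E[j] <- E[j] + d * nj / n
      for (jj in seq_len(k)) {
        njj <- sum(risk & group == levels(group)[jj])
        if (n > 1)
          V[j, jj] <- V[j, jj] + d * (n - d) / (n - 1) *
            (nj / n) * ((j == jj) - njj / n)
      }
    }
  }
  u <- (O - E)[-k]
  drop(crossprod(u, solve(V[-k, -k, drop = FALSE], u)))
}

# Quartile labels by the stated rule, done by sorting and direct counting.
brute_quartiles <- function(scores) {
  cuts <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  vapply(scores, function(v) {
    if (v <= cuts[1]) 1L else if (v <= cuts[2]) 2L
    else if (v <= cuts[3]) 3L else 4L
  }, integer(1))
}

# Small random survival instance for oracle-equivalence checks.
random_small_instance <- function(n = 8L) {
  list(time = sample(1:20, n, replace = TRUE) + stats::runif(n) * 0.5,
       event = stats::rbinom(n, 1, 0.7),
       x = round(stats::rnorm(n), 2))
}
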