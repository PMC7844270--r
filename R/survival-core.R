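#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function under right censoring:
#' \deqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times \eqn{t_i}, with \eqn{d_i} deaths and
#' \eqn{n_i} subjects at risk. At tied times deaths are processed before
#' censorings, i.e. a subject censored at \eqn{t_i} is still in the risk set
#' at \eqn{t_i} (standard convention).
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group optional single label attached to the curve.
#' @return object of class `nim_km`: a list with `time` (distinct event
#'   times, sorted), `surv` (survival just after each event time), `n_risk`,
#'   `n_event`, `n`, and `group`.
#' @export
km_curve <- function(time, event, group = NULL) {
  check_surv_input(time, event)
  if (length(time) == 0L) stop("no records supplied")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = length(time), group = group),
            class = "nim_km")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' The estimate is a right-continuous step function starting at 1.
#'
#' @param curve object from [km_curve()].
#' @param t numeric times (months).
#' @return survival probabilities at `t`.
#' @export
km_survival <- function(curve, t) {
  stopifnot(inherits(curve, "nim_km"))
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' @export
print.nim_km <- function(x, ...) {
  cat("Kaplan-Meier curve", if (!is.null(x$group)) paste0("[", x$group, "]"),
      "\n  n =", x$n, ", events =", sum(x$n_event),
      ", final S =", format(x$surv[length(x$surv)], digits = 4), "\n")
  invisible(x)
}

#' As a data frame, one row per distinct event time
#' @param x object from [km_curve()].
#' @param ... unused.
#' @export
as.data.frame.nim_km <- function(x, ...) {
  data.frame(group = if (is.null(x$group)) NA_character_ else x$group,
             time = x$time, surv = x$surv,
             n_risk = x$n_risk, n_event = x$n_event)
}

#' K-sample log-rank test
#'
#' Tests equality of survivor functions across groups. At each distinct
#' event time the observed deaths per group are compared with their
#' hypergeometric expectation given the risk sets; the per-time differences
#' are aggregated with the hypergeometric covariance and the chi-squared
#' statistic is formed on k - 1 dimensions (generalized inverse when the
#' covariance is singular).
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group group label per record (>= 2 groups).
#' @return object of class `nim_logrank`: list with `chi2`, `df`
#'   (groups - 1), `p`, and the per-group `observed` and `expected` totals.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  group <- as.factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("log-rank test needs at least 2 groups")
  if (sum(event) == 0L) stop("log-rank test needs at least 1 event")
  et <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- tabulate(group[at_risk], nbins = k)
    died <- time == t & event == 1
    d <- sum(died)
    dj <- tabulate(group[died], nbins = k)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      pj <- nj / n
      V <- V + d * (n - d) / (n - 1) * (diag(pj, k) - outer(pj, pj))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(drop(crossprod(u, solve(Vk, u))),
                   error = function(e) drop(crossprod(u, pseudo_inverse(Vk) %*% u)))
  structure(list(chi2 = max(chi2, 0), df = k - 1L,
                 p = stats::pchisq(max(chi2, 0), k - 1L, lower.tail = FALSE),
                 observed = O, expected = E, groups = levels(group)),
            class = "nim_logrank")
}

#' @export
print.nim_logrank <- function(x, ...) {
  cat("Log-rank test: chi2(", x$df, ") = ", format(x$chi2, digits = 5),
      ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Stratified Cox proportional-hazards fit
#'
#' Maximizes the stratified partial likelihood (the sum of per-stratum log
#' partial likelihoods; each stratum has its own unspecified baseline
#' hazard) by Newton-Raphson with step-halving. Ties are handled by the
#' Efron approximation by default, or Breslow's; the two agree exactly on
#' tie-free data. Standard errors come from the inverse observed
#' information. Convergence is declared when the relative change in the log
#' partial likelihood falls below `tol` (default 1e-9, at most `max_iter`
#' iterations). A coefficient diverging past `|beta| > 20` is taken as
#' monotone likelihood (separation) and flagged as non-convergence.
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param x numeric covariate matrix (columns named).
#' @param strata optional stratum label per record; `NULL` = one stratum.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param center subtract pooled covariate means before fitting (affects
#'   only the implicit baseline, not coefficients or standard errors).
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class `nim_cox`: list with `coef`, `se`, `var`
#'   (covariance matrix), `loglik` (at solution), `loglik_null` (at beta =
#'   0), `score` (gradient at solution), `iter`, `converged`, `n`,
#'   `n_event`, `ties`.
#' @export
cox_fit <- function(time, event, x, strata = NULL,
                    ties = c("efron", "breslow"), center = TRUE,
                    max_iter = 100L, tol = 1e-9) {
  ties <- match.arg(ties)
  check_surv_input(time, event)
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x))) stop("covariates must be finite numeric")
  if (nrow(x) != length(time)) stop("covariate rows must match record count")
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (qr(x)$rank < p) {
    stop("collinear covariates: ", paste(colnames(x), collapse = ", "),
         " do not have full column rank")
  }
  if (isTRUE(center)) x <- sweep(x, 2L, colMeans(x))
  if (is.null(strata)) strata <- rep(1L, length(time))
  strata <- as.factor(strata)
  ev_per_str <- tapply(event, strata, sum)
  if (any(ev_per_str == 0))
    warning("stratum with no events contributes nothing to the partial likelihood: ",
            paste(names(ev_per_str)[ev_per_str == 0], collapse = ", "))

  # Pre-sort each stratum by decreasing time so risk-set sums are cumsums.
  parts <- lapply(split(seq_along(time), strata), function(idx) {
    o <- idx[order(time[idx], decreasing = TRUE)]
    ts <- time[o]; ev <- event[o]
    # tie groups of event times: risk set end = last position with ts >= t
    et <- unique(ts[ev == 1])
    groups <- lapply(et, function(t) {
      list(risk_end = max(which(ts == t)), deaths = which(ts == t & ev == 1))
    })
    list(X = x[o, , drop = FALSE], eta_idx = o, ts = ts, ev = ev, groups = groups)
  })

  ppairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  unpack_sym <- function(v) {
    m <- matrix(0, p, p)
    m[ppairs] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }

  eval_pl <- function(beta) {
    ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
    for (st in parts) {
      eta <- drop(st$X %*% beta)
      w <- exp(eta)
      wX <- st$X * w
      wXX <- st$X[, ppairs[, 1], drop = FALSE] * st$X[, ppairs[, 2], drop = FALSE] * w
      cw <- cumsum(w)
      cwX <- apply(wX, 2L, cumsum)
      cwXX <- apply(wXX, 2L, cumsum)
      if (is.null(dim(cwX))) { cwX <- matrix(cwX, nrow = 1); cwXX <- matrix(cwXX, nrow = 1) }
      for (g in st$groups) {
        r <- g$risk_end; D <- g$deaths; d <- length(D)
        S0 <- cw[r]; S1 <- cwX[r, ]; S2 <- cwXX[r, ]
        ll <- ll + sum(eta[D])
        grad <- grad + colSums(st$X[D, , drop = FALSE])
        if (ties == "efron" && d > 1L) {
          sd0 <- sum(w[D]); sd1 <- colSums(wX[D, , drop = FALSE])
          sd2 <- colSums(wXX[D, , drop = FALSE])
          for (l in seq_len(d) - 1L) {
            f <- l / d
            s0 <- S0 - f * sd0; s1 <- S1 - f * sd1; s2 <- S2 - f * sd2
            ll <- ll - log(s0)
            grad <- grad - s1 / s0
            info <- info + unpack_sym(s2) / s0 - tcrossprod(s1 / s0)
          }
        } else {
          ll <- ll - d * log(S0)
          grad <- grad - d * S1 / S0
          info <- info + d * (unpack_sym(S2) / S0 - tcrossprod(S1 / S0))
        }
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- numeric(p)
  cur <- eval_pl(beta)
  loglik_null <- cur$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e)
      stop("singular information matrix (collinear covariates?): ",
           paste(colnames(x), collapse = ", ")))
    cand <- beta + step
    nxt <- eval_pl(cand)
    halvings <- 0L
    while (!is.finite(nxt$ll) || nxt$ll < cur$ll) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      cand <- beta + step / 2^halvings
      nxt <- eval_pl(cand)
    }
    dll <- abs(nxt$ll - cur$ll)
    beta <- cand
    cur <- nxt
    if (dll < tol * (abs(cur$ll) + tol)) { converged <- TRUE; break }
  }
  if (any(abs(beta) > 20)) converged <- FALSE  # monotone likelihood / separation
  vcov <- tryCatch(solve(cur$info), error = function(e)
    stop("singular information matrix at solution: ",
         paste(colnames(x), collapse = ", ")))
  names(beta) <- colnames(x)
  se <- sqrt(diag(vcov))
  names(se) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(list(coef = beta, se = se, var = vcov, loglik = cur$ll,
                 loglik_null = loglik_null, score = cur$grad, iter = iter,
                 converged = converged, n = length(time),
                 n_event = sum(event), ties = ties),
            class = "nim_cox")
}

#' @export
print.nim_cox <- function(x, digits = 4, ...) {
  cat("Stratified Cox proportional-hazards fit (", x$ties, " ties)\n",
      "  n = ", x$n, ", events = ", x$n_event,
      ", loglik = ", format(x$loglik, digits = 8),
      ", iterations = ", x$iter,
      if (!x$converged) "  [NOT CONVERGED]", "\n\n", sep = "")
  print(model_report(x)[, c("term", "hr", "se_hr", "z", "p", "ci_lo", "ci_hi")],
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Hazard-ratio report for a Cox fit
#'
#' Presents a fit on the hazard-ratio scale: HR = exp(coef), the standard
#' error on the HR scale by the delta method (se_HR = HR * se_coef), Wald z
#' and p, the 95\% normal-approximation confidence interval
#' exp(coef +/- 1.96 se), and the percent change in hazard 100 (HR - 1).
#' AIC = -2 loglik + 2k and BIC = -2 loglik + k log(n) are attached as
#' attributes; BIC uses the number of subjects by default (`bic_n =
#' "events"` uses the number of events instead — conventions differ).
#'
#' @param fit object from [cox_fit()].
#' @param bic_n sample-size convention for BIC: `"subjects"` or `"events"`.
#' @return data.frame with one row per covariate and columns `term`, `coef`,
#'   `hr`, `se_hr`, `z`, `p`, `ci_lo`, `ci_hi`, `pct_change`; attributes
#'   `loglik`, `AIC`, `BIC`, `unconverged`.
#' @export
model_report <- function(fit, bic_n = c("subjects", "events")) {
  stopifnot(inherits(fit, "nim_cox"))
  bic_n <- match.arg(bic_n)
  if (!fit$converged)
    warning("reporting an unconverged fit; estimates may be unreliable")
  hr <- exp(fit$coef)
  z <- fit$coef / fit$se
  out <- data.frame(
    term = names(fit$coef),
    coef = unname(fit$coef),
    hr = unname(hr),
    se_hr = unname(hr * fit$se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    ci_lo = unname(exp(fit$coef - 1.96 * fit$se)),
    ci_hi = unname(exp(fit$coef + 1.96 * fit$se)),
    pct_change = unname(100 * (hr - 1)),
    stringsAsFactors = FALSE)
  k <- length(fit$coef)
  nn <- if (bic_n == "subjects") fit$n else fit$n_event
  attr(out, "loglik") <- fit$loglik
  attr(out, "AIC") <- -2 * fit$loglik + 2 * k
  attr(out, "BIC") <- -2 * fit$loglik + k * log(nn)
  attr(out, "unconverged") <- !fit$converged
  out
}

check_surv_input <- function(time, event) {
  if (length(time) != length(event)) stop("`time` and `event` lengths differ")
  if (anyNA(time) || anyNA(event)) stop("missing values in survival data")
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
}

# Moore-Penrose pseudo-inverse via SVD (used when a log-rank covariance
# block is singular, e.g. a group with an empty risk set throughout).
pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
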