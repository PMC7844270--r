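#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-study log-hazard-ratio estimates with weights
#' \eqn{w_i = 1/se_i^2}: pooled \eqn{\hat\beta = \sum w_i \beta_i / \sum
#' w_i}, pooled \eqn{se = (\sum w_i)^{-1/2}}. Heterogeneity is summarized by
#' Cochran's \eqn{Q = \sum w_i (\beta_i - \hat\beta)^2} (chi-squared with
#' k - 1 df under homogeneity) and \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100}.
#'
#' @param beta numeric log-hazard-ratio estimates (>= 2).
#' @param se positive standard errors, same length.
#' @param labels optional study labels.
#' @return object of class `nim_meta`: list with `pooled`, `pooled_se`,
#'   `Q`, `df`, `p`, `I2` (percent), and the per-study `studies` table.
#' @examples
#' fixed_effect_meta(c(0, 1), c(1, 1))  # pooled 0.5, Q 0.5, I2 0
#' @export
fixed_effect_meta <- function(beta, se, labels = NULL) {
  if (length(beta) < 2L) stop("need at least 2 study estimates, got ", length(beta))
  if (length(se) != length(beta)) stop("`beta` and `se` lengths differ")
  if (anyNA(beta) || anyNA(se)) stop("missing study estimates")
  if (any(se <= 0)) stop("standard errors must be positive")
  if (is.null(labels)) labels <- paste0("study", seq_along(beta))
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  Q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(pooled = pooled, pooled_se = pooled_se, Q = Q, df = df,
                 p = stats::pchisq(Q, df, lower.tail = FALSE), I2 = I2,
                 studies = data.frame(label = labels, beta = beta, se = se,
                                      weight = w / sum(w),
                                      stringsAsFactors = FALSE)),
            class = "nim_meta")
}

#' @export
print.nim_meta <- function(x, ...) {
  cat("Fixed-effect meta-analysis (", nrow(x$studies), " studies)\n",
      "  pooled beta = ", format(x$pooled, digits = 4),
      " (HR ", format(exp(x$pooled), digits = 4), "), se = ",
      format(x$pooled_se, digits = 4), "\n",
      "  Cochran's Q = ", format(x$Q, digits = 4), " (df ", x$df,
      ", p = ", format.pval(x$p, digits = 3), "), I2 = ",
      format(x$I2, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Two-stage individual-participant-data meta-analysis
#'
#' Stage 1 fits the sex-stratified Cox model separately within each dataset;
#' stage 2 pools the coefficient of interest (by default the highest-vs-
#' lowest quartile contrast, the headline comparison) across datasets by
#' fixed-effect inverse-variance weighting. This complements the one-stage
#' dataset-and-sex-stratified fit: the pooled estimate should agree closely,
#' and Q / I-squared quantify between-cohort heterogeneity of the effect.
#'
#' @param table participant table with NIM quartiles (from [compute_nim()])
#'   and columns `dataset`, `sex`, `age`, `bmi`, `ethnicity`, `time`,
#'   `event`.
#' @param term coefficient to pool (default `"quartile4"`; any covariate
#'   name of the fitted model is allowed).
#' @param ties tie-handling rule passed to [cox_fit()].
#' @return `nim_meta` object (see [fixed_effect_meta()]); the per-dataset
#'   `nim_cox` fits are attached as attribute `"fits"`.
#' @export
two_stage_meta <- function(table, term = "quartile4",
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  datasets <- unique(as.character(table$dataset))
  if (length(datasets) < 2L)
    stop("two-stage meta-analysis needs >= 2 datasets, got ", length(datasets))
  fits <- lapply(datasets, function(d) {
    sub <- table[table$dataset == d, , drop = FALSE]
    if (sum(sub$event) == 0L)
      stop("dataset '", d, "' has no events; stage-1 fit impossible")
    fit <- tryCatch(
      nim_cox_fit(sub, ties = ties, strata_by_dataset = FALSE),
      error = function(e) stop("stage-1 fit failed in dataset '", d, "': ",
                               conditionMessage(e)))
    if (!fit$converged)
      stop("stage-1 fit did not converge in dataset '", d, "'")
    fit
  })
  names(fits) <- datasets
  beta <- vapply(fits, function(f) f$coef[[term]], numeric(1))
  se <- vapply(fits, function(f) f$se[[term]], numeric(1))
  out <- fixed_effect_meta(beta, se, labels = datasets)
  attr(out, "term") <- term
  attr(out, "fits") <- fits
  out
}
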