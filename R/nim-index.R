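#' Stratum-wise z-transformation
#'
#' Standardizes measurements within each stratum (here: dataset), so that a
#' value is expressed relative to its own cohort's distribution. Uses the
#' sample standard deviation (denominator n - 1).
#'
#' @param values numeric measurements.
#' @param strata stratum label per value (e.g. dataset).
#' @return numeric vector of z-scores; within every stratum the output has
#'   mean 0 and sd 1 (to numerical precision).
#' @export
zscore_by_stratum <- function(values, strata) {
  if (length(values) != length(strata))
    stop("`values` and `strata` must have equal length")
  if (anyNA(values)) stop("`values` contains missing values")
  strata <- as.character(strata)
  out <- numeric(length(values))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2L)
      stop("stratum '", s, "' has fewer than 2 values; cannot standardize")
    sd_s <- stats::sd(values[idx])
    if (sd_s == 0)
      stop("stratum '", s, "' has zero variance; cannot standardize")
    out[idx] <- (values[idx] - mean(values[idx])) / sd_s
  }
  out
}

#' Neuroimmunomodulation (NIM) score from standardized components
#'
#' Combines the standardized vagal tone measure (z of RMSSD) with a
#' standardized inflammatory marker (z of CRP or IL-6) into a single score
#' in which higher values indicate more vagal inhibition of inflammation.
#'
#' Two scoring rules are provided. `"difference"` (the default) computes
#' `z_rmssd - z_marker`: it is monotone increasing in vagal tone and
#' decreasing in inflammation everywhere, and never degenerate. `"ratio"`
#' computes the literal quotient `z_rmssd / z_marker`; because the
#' denominator is a mean-zero z-score, the quotient blows up and changes
#' monotonicity near zero, so scores with `|z_marker| < eps` are flagged
#' (value set to `NA`) rather than propagated. Downstream analysis uses only
#' quartile membership, for which the difference is the well-behaved
#' monotone analogue of the ratio.
#'
#' @param z_rmssd,z_marker finite numeric vectors of equal length.
#' @param method `"difference"` (default) or `"ratio"`.
#' @param eps degeneracy guard for the ratio denominator (default 0.05).
#' @return list with components `value` (numeric; `NA` where flagged) and
#'   `flagged` (logical).
#' @export
nim_score <- function(z_rmssd, z_marker,
                      method = c("difference", "ratio"), eps = 0.05) {
  method <- match.arg(method)
  if (length(z_rmssd) != length(z_marker))
    stop("`z_rmssd` and `z_marker` must have equal length")
  if (!all(is.finite(z_rmssd)) || !all(is.finite(z_marker)))
    stop("non-finite z-score input")
  if (method == "difference") {
    list(value = z_rmssd - z_marker,
         flagged = rep(FALSE, length(z_rmssd)))
  } else {
    flagged <- abs(z_marker) < eps
    value <- ifelse(flagged, NA_real_, z_rmssd / z_marker)
    list(value = value, flagged = flagged)
  }
}

#' Assign quartile risk groups to pooled NIM scores
#'
#' Cutpoints are the empirical 25th/50th/75th percentiles of the pooled
#' usable (finite, unflagged) scores, using the linear-interpolation
#' percentile definition (`quantile(type = 7)`). A score equal to a cutpoint
#' goes to the lower group, so quartile 1 is `score <= Q25` and quartile 4
#' is `score > Q75`. Flagged scores receive `NA`.
#'
#' @param scores numeric NIM scores pooled across datasets (`NA` = flagged).
#' @return integer vector of quartile labels in 1..4 (`NA` where the score
#'   was unusable), with the cutpoints attached as attribute `"cutpoints"`.
#' @export
assign_quartiles <- function(scores) {
  usable <- is.finite(scores)
  if (sum(usable) < 4L)
    stop("need at least 4 usable NIM scores to form quartiles, got ",
         sum(usable))
  cuts <- stats::quantile(scores[usable], probs = c(0.25, 0.5, 0.75),
                          names = FALSE, type = 7)
  q <- rep(NA_integer_, length(scores))
  q[usable] <- 1L +
    (scores[usable] > cuts[1]) +
    (scores[usable] > cuts[2]) +
    (scores[usable] > cuts[3])
  attr(q, "cutpoints") <- cuts
  q
}

#' Compute the NIM index and quartiles for a participant table
#'
#' Runs the full index construction: z-transforms RMSSD and the chosen
#' inflammatory marker within each dataset, combines them into the NIM score,
#' and assigns quartiles on the scores pooled across datasets (the
#' dataset-wise standardization is what makes pooling meaningful;
#' `pool_quartiles = FALSE` quartiles within each dataset instead).
#'
#' @param table data.frame with columns `dataset`, `rmssd`, and the chosen
#'   marker (`il6` or `crp`).
#' @param marker `"IL6"` or `"CRP"`.
#' @param method scoring rule, see [nim_score()].
#' @param log_markers apply a natural-log transform to RMSSD and the marker
#'   before standardizing (default `FALSE`: raw values are standardized).
#' @param pool_quartiles quartile on pooled scores (default) or per dataset.
#' @return the input table with columns `z_rmssd`, `z_marker`, `nim`,
#'   `quartile`, `flagged` appended.
#' @export
compute_nim <- function(table, marker = c("IL6", "CRP"),
                        method = c("difference", "ratio"),
                        log_markers = FALSE, pool_quartiles = TRUE) {
  marker <- match.arg(marker)
  method <- match.arg(method)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("`table` must be a non-empty data.frame")
  mcol <- tolower(marker)
  need <- c("dataset", "rmssd", mcol)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  x_rmssd <- table$rmssd
  x_marker <- table[[mcol]]
  if (isTRUE(log_markers)) {
    if (any(x_rmssd <= 0) || any(x_marker <= 0))
      stop("log transform requires strictly positive RMSSD and marker values")
    x_rmssd <- log(x_rmssd)
    x_marker <- log(x_marker)
  }
  table$z_rmssd <- zscore_by_stratum(x_rmssd, table$dataset)
  table$z_marker <- zscore_by_stratum(x_marker, table$dataset)
  sc <- nim_score(table$z_rmssd, table$z_marker, method = method)
  table$nim <- sc$value
  table$flagged <- sc$flagged
  if (pool_quartiles) {
    table$quartile <- assign_quartiles(table$nim)
  } else {
    q <- rep(NA_integer_, nrow(table))
    for (d in unique(table$dataset)) {
      idx <- table$dataset == d
      q[idx] <- assign_quartiles(table$nim[idx])
    }
    table$quartile <- q
  }
  attr(table, "nim_marker") <- marker
  attr(table, "nim_method") <- method
  table
}

#' Per-quartile descriptive summary of a NIM-scored table
#'
#' Emits the descriptive layout used to characterize the index: per quartile
#' (within each dataset and overall) the number of participants and the mean
#' and standard deviation of RMSSD and of the inflammatory marker.
#'
#' @param table output of [compute_nim()].
#' @return data.frame with one row per dataset-by-quartile cell plus pooled
#'   rows (`dataset = "Total"`).
#' @export
nim_quartile_summary <- function(table) {
  if (is.null(table$quartile)) stop("`table` has no `quartile` column; run compute_nim() first")
  marker <- attr(table, "nim_marker")
  mcol <- tolower(if (is.null(marker)) "il6" else marker)
  cells <- expand.grid(dataset = c(unique(as.character(table$dataset)), "Total"),
                       quartile = sort(unique(stats::na.omit(table$quartile))),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$dataset[i]; q <- cells$quartile[i]
    idx <- !is.na(table$quartile) & table$quartile == q &
      (d == "Total" | table$dataset == d)
    data.frame(dataset = d, quartile = q, n = sum(idx),
               rmssd_mean = mean(table$rmssd[idx]),
               rmssd_sd = stats::sd(table$rmssd[idx]),
               marker_mean = mean(table[[mcol]][idx]),
               marker_sd = stats::sd(table[[mcol]][idx]))
  })
  out <- do.call(rbind, rows)
  out[order(out$dataset, out$quartile), , drop = FALSE]
}
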