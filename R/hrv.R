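#' Root mean square of successive differences (RMSSD)
#'
#' Computes the standard time-domain vagally-mediated heart rate variability
#' measure from an ordered series of interbeat intervals:
#' \deqn{RMSSD = \sqrt{\frac{1}{n-1}\sum_{i=1}^{n-1}(x_{i+1}-x_i)^2}}
#' where the denominator is the number of successive differences (task-force
#' convention; some software divides by n, which differs by one index).
#'
#' No ectopic-beat correction is applied by default: the series is assumed to
#' be a clean normal-to-normal tachogram. `artifact_filter = TRUE` drops any
#' interval deviating more than 25\% from the running median (window 11,
#' shrunk for short series) before computing RMSSD.
#'
#' @param intervals numeric vector of interbeat intervals in milliseconds,
#'   in recording order; length >= 2, all values > 0.
#' @param artifact_filter logical; drop intervals deviating > 25\% from the
#'   running median. Default `FALSE`.
#' @return RMSSD in milliseconds (non-negative scalar; zero iff the series
#'   is constant).
#' @examples
#' rmssd(c(800, 810))            # 10
#' rmssd(c(800, 810, 790, 805))  # sqrt(725/3)
#' @export
rmssd <- function(intervals, artifact_filter = FALSE) {
  if (!is.numeric(intervals)) stop("`intervals` must be numeric")
  if (anyNA(intervals)) stop("`intervals` contains missing values")
  if (any(intervals <= 0)) stop("interbeat intervals must be positive (ms)")
  if (isTRUE(artifact_filter)) intervals <- filter_artifacts(intervals)
  n <- length(intervals)
  if (n < 2L) stop("need at least 2 interbeat intervals, got ", n)
  d <- diff(intervals)
  sqrt(sum(d^2) / (n - 1L))
}

# Running-median artifact screen: window 11 (or largest odd window that
# fits), relative deviation threshold 25%.
filter_artifacts <- function(intervals, threshold = 0.25, window = 11L) {
  n <- length(intervals)
  k <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(intervals)
  med <- stats::runmed(intervals, k, endrule = "median")
  keep <- abs(intervals - med) <= threshold * med
  intervals[keep]
}

#' Average per-segment RMSSD values
#'
#' The study design records two 5-minute resting ECG segments per subject;
#' the per-segment RMSSD values are averaged. When only one segment is valid
#' or available, the single value is used unchanged. More than two values is
#' an error: the design is two-segment.
#'
#' @param values numeric vector of one or two non-negative per-segment RMSSD
#'   values in milliseconds.
#' @return arithmetic mean of the provided values, in milliseconds.
#' @examples
#' average_segments(c(12, 18))  # 15
#' average_segments(12)         # 12
#' @export
average_segments <- function(values) {
  if (!is.numeric(values) || anyNA(values))
    stop("`values` must be numeric without missing values")
  if (length(values) == 0L) stop("no segment RMSSD values provided")
  if (length(values) > 2L)
    stop("at most two 5-min segments are defined; got ", length(values))
  if (any(values < 0)) stop("RMSSD values must be non-negative")
  mean(values)
}

#' Read an interbeat-interval series from a plain-text file
#'
#' One interval in milliseconds per line; blank lines and `#` comment lines
#' are ignored.
#'
#' @param path path to a text file.
#' @return numeric vector of intervals in milliseconds.
#' @export
read_ibi <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) stop("non-numeric interbeat interval in ", path)
  x
}
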