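#' Write a participant table to CSV
#'
#' Uses the study schema `id,dataset,sex,ethnicity,age,bmi,rmssd,crp,il6,
#' time_months,event`, with missing values as empty fields. Header comment
#' lines record the generating seed (when known) and a short hash of the
#' generating specifications, so a file can be traced to its configuration.
#'
#' @param table participant data.frame (internal column `time` is written
#'   as `time_months`).
#' @param path output path.
#' @param seed generating seed; defaults to the table's `"seed"` attribute.
#' @param specs optional list of generating spec objects, hashed into the
#'   header.
#' @return `path`, invisibly.
#' @export
write_study <- function(table, path, seed = attr(table, "seed"), specs = NULL) {
  check_study_schema(table)
  out <- table[, c("id", "dataset", "sex", "ethnicity", "age", "bmi",
                   "rmssd", "crp", "il6", "time", "event")]
  names(out)[names(out) == "time"] <- "time_months"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# spec_hash: %s",
            if (is.null(specs)) "NA" else spec_hash(specs))), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a participant table from CSV
#'
#' Reads the study schema written by [write_study()] (comment lines
#' starting with `#` are skipped, empty fields become `NA`) and validates
#' the columns.
#'
#' @param path CSV path.
#' @return participant data.frame with internal column names (`time`,
#'   `event`).
#' @export
read_study <- function(path) {
  table <- utils::read.csv(path, comment.char = "#", na.strings = "",
                           stringsAsFactors = FALSE)
  names(table)[names(table) == "time_months"] <- "time"
  check_study_schema(table)
  table
}

check_study_schema <- function(table) {
  need <- c("id", "dataset", "sex", "ethnicity", "age", "bmi", "rmssd",
            "crp", "il6", "time", "event")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("participant table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(table[, need])
  bad <- which(complete &
                 (table$time <= 0 | !(table$event %in% c(0, 1)) |
                    table$rmssd <= 0 | table$crp <= 0 | table$il6 <= 0))
  if (length(bad))
    stop("invalid values (non-positive time/biomarker or event not 0/1) in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  invisible(TRUE)
}

# 32-bit multiplicative (djb2-style) hash of the deparsed object, as 8 hex
# digits; arithmetic kept below 2^53 so doubles stay exact.
spec_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Serialize generator specifications to YAML
#'
#' Writes cohort, coupling and survival specifications as a YAML config
#' block that [specs_from_yaml()] reconstructs exactly.
#'
#' @param specs list with any of `cohorts` (named list of [cohort_spec()]),
#'   `coupling` ([coupling_spec()]), `survival` ([survival_spec()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
specs_to_yaml <- function(specs, path) {
  strip <- function(x) lapply(unclass(x), function(v)
    if (is.null(names(v))) v else as.list(v))
  doc <- list()
  if (!is.null(specs$cohorts)) doc$cohorts <- lapply(specs$cohorts, strip)
  if (!is.null(specs$coupling)) doc$coupling <- strip(specs$coupling)
  if (!is.null(specs$survival)) doc$survival <- strip(specs$survival)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read generator specifications from YAML
#'
#' @param path YAML file written by [specs_to_yaml()].
#' @return list with the reconstructed spec objects (`cohorts`, `coupling`,
#'   `survival`, whichever the file contains).
#' @export
specs_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(doc$cohorts))
    out$cohorts <- lapply(doc$cohorts, function(x) do.call(cohort_spec, x))
  if (!is.null(doc$coupling))
    out$coupling <- do.call(coupling_spec, doc$coupling)
  if (!is.null(doc$survival)) {
    sv <- doc$survival
    sv$beta_quartile <- as.numeric(unlist(sv$beta_quartile))
    sv$baseline_rate <- unlist(sv$baseline_rate)
    out$survival <- do.call(survival_spec, sv)
  }
  out
}
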