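# Frozen output of calibrate_generator() run with the default targets
# (overall death fraction 0.111; 216-month KM survival 0.75/0.91 in the
# lowest/highest quartile for the IL-6 index, 0.79/0.91 for CRP), default
# cohort and coupling specs, and the marker's default survival effects.
# Regenerate with calibrate_generator(); see the methods vignette.
.nim_calibration <- list(
  IL6 = list(rate_multiplier = 1.0905077327, age_coupling_scale = 1.0),
  CRP = list(rate_multiplier = 1.0, age_coupling_scale = 1.0))

#' Frozen calibration constants of the default generator
#'
#' The shared baseline-rate multiplier and the age-coupling scale that make
#' the default synthetic study reproduce the marginal targets (overall
#' death fraction and the 216-month quartile survival fractions) while the
#' generating hazard ratios stay at the reference values. They are the
#' stored result of [calibrate_generator()] under the default
#' specifications and can be regenerated with it.
#'
#' @param marker `"IL6"` or `"CRP"`.
#' @return list with `rate_multiplier` and `age_coupling_scale`.
#' @export
calibration_defaults <- function(marker = c("IL6", "CRP")) {
  marker <- match.arg(marker)
  .nim_calibration[[marker]]
}
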