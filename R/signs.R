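#' Numeric clinical signs handled by the package
#'
#' The seven numeric signs a digital consultation tool prompts for:
#' temperature, mid-upper arm circumference (MUAC), weight, height, heart
#' rate, respiratory rate and blood oxygen saturation (SpO2). Three derived
#' growth indicators (MUAC-for-age, weight-for-age, weight-for-height
#' z-scores) are listed separately.
#'
#' @format Character vectors.
#' @name sign_ids
NULL

#' @rdname sign_ids
#' @export
SIGN_IDS <- c("temperature", "muac", "weight", "height",
              "heart_rate", "resp_rate", "spo2")

#' @rdname sign_ids
#' @export
Z_INDICATORS <- c("muac_for_age", "weight_for_age", "weight_for_height")

# sign whose raw measurement feeds each growth indicator
Z_SOURCE_SIGN <- c(muac_for_age = "muac",
                   weight_for_age = "weight",
                   weight_for_height = "weight")

# age window (days) for growth z-scores: 2 months to 5 years
Z_AGE_MIN_DAYS <- 61L
Z_AGE_MAX_DAYS <- 1826L

# MUAC is prompted only above 6 months of age
MUAC_MIN_AGE_DAYS <- 182L

#' Declare a numeric sign and its baseline generating distribution
#'
#' A `sign_spec` bundles everything the cohort generator and the summary
#' layer need to know about one sign: the recording grid (the decimal step
#' the tool accepts), which children are prompted for it, the baseline rate
#' of "not feasible" entries, and the baseline value distribution.
#'
#' Two distribution families are supported: a truncated normal
#' (`dist = list(type = "normal", mean, sd, lower, upper)`) for vitals and
#' temperature, and a log-normal ride on a growth median curve
#' (`dist = list(type = "growth", indicator, sigma)`) for anthropometry,
#' where `indicator` names the median curve (see [growth_median()]) and
#' `sigma` the log-scale spread.
#'
#' @param sign_id One of `SIGN_IDS`.
#' @param unit Measurement unit label.
#' @param precision Recording step (> 0), e.g. 0.1 for temperature in
#'   degrees Celsius, 1 for beats per minute.
#' @param eligibility One of `"all"`, `"age_over_6m"`,
#'   `"respiratory_complaint"`.
#' @param not_feasible_rate Baseline probability that the measurement is
#'   marked not feasible, in `[0, 1]`.
#' @param dist Baseline distribution description (see Details).
#' @param estimated_rate Probability that a weight is entered as "estimated"
#'   rather than measured (weight only; estimated values are treated as
#'   missing downstream).
#' @return An object of class `sign_spec`.
#' @export
sign_spec <- function(sign_id, unit, precision, eligibility,
                      not_feasible_rate, dist, estimated_rate = 0) {
  sign_id <- match.arg(sign_id, SIGN_IDS)
  eligibility <- match.arg(eligibility,
                           c("all", "age_over_6m", "respiratory_complaint"))
  stopifnot(is.numeric(precision), length(precision) == 1L, precision > 0)
  if (!is.numeric(not_feasible_rate) || not_feasible_rate < 0 ||
      not_feasible_rate > 1) {
    stop("`not_feasible_rate` must be a probability in [0, 1]", call. = FALSE)
  }
  if (estimated_rate > 0 && sign_id != "weight") {
    stop("only weight can carry an 'estimated' status", call. = FALSE)
  }
  stopifnot(is.list(dist), dist$type %in% c("normal", "growth"))
  structure(
    list(sign_id = sign_id, unit = unit, precision = precision,
         eligibility = eligibility, not_feasible_rate = not_feasible_rate,
         dist = dist, estimated_rate = estimated_rate),
    class = "sign_spec"
  )
}

#' Default sign specifications
#'
#' Baseline conditions for the synthetic cohort: plausible value
#' distributions per sign, recording precisions matching the tool's data
#' formats, eligibility rules (MUAC above 6 months; heart rate, respiratory
#' rate and SpO2 only for respiratory complaints) and modest baseline
#' not-feasible rates.
#'
#' @return Named list of [sign_spec()] objects, one per sign.
#' @export
default_sign_specs <- function() {
  list(
    temperature = sign_spec(
      "temperature", "degC", 0.1, "all", 0.03,
      dist = list(type = "normal", mean = 36.8, sd = 0.5,
                  lower = 35, upper = 41)),
    muac = sign_spec(
      "muac", "cm", 0.1, "age_over_6m", 0.06,
      dist = list(type = "growth", indicator = "muac_for_age",
                  sigma = 0.07)),
    weight = sign_spec(
      "weight", "kg", 0.1, "all", 0,
      dist = list(type = "growth", indicator = "weight_for_age",
                  sigma = 0.12),
      estimated_rate = 0.03),
    height = sign_spec(
      "height", "cm", 0.1, "all", 0.05,
      dist = list(type = "growth", indicator = "height_for_age",
                  sigma = 0.04)),
    heart_rate = sign_spec(
      "heart_rate", "beats/min", 1, "respiratory_complaint", 0.10,
      dist = list(type = "normal", mean = 120, sd = 20,
                  lower = 40, upper = 220)),
    resp_rate = sign_spec(
      "resp_rate", "breaths/min", 1, "respiratory_complaint", 0.12,
      dist = list(type = "normal", mean = 35, sd = 10,
                  lower = 10, upper = 90)),
    spo2 = sign_spec(
      "spo2", "%", 1, "respiratory_complaint", 0.10,
      dist = list(type = "normal", mean = 97, sd = 1.8,
                  lower = 80, upper = 100))
  )
}

#' Snap values to a sign's recording grid
#'
#' @param x Numeric vector.
#' @param precision Recording step (> 0).
#' @return `x` rounded to the nearest multiple of `precision`, cleaned of
#'   floating-point dust so grid values compare equal.
#' @export
quantize <- function(x, precision) {
  stopifnot(precision > 0)
  digits <- max(0L, ceiling(-log10(precision)) + 1L)
  round(round(x / precision) * precision, digits)
}

# eligibility mask for a sign given consultation covariates
sign_eligible <- function(spec, age_days, respiratory_complaint) {
  switch(spec$eligibility,
         all = rep(TRUE, length(age_days)),
         age_over_6m = age_days > MUAC_MIN_AGE_DAYS,
         respiratory_complaint = respiratory_complaint)
}
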