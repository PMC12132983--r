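#' Declare an injectable measurement behaviour
#'
#' The four facility-level behaviours the pattern classifier is built to
#' detect, expressed as distortions of one facility-sign pair:
#'
#' * `skipper`: raises the not-feasible (missing) rate by `intensity`.
#' * `mono_repeater`: moves probability mass `intensity` onto one target
#'   value (heaping on a single value).
#' * `multi_repeater`: moves mass `intensity` onto 2-3 target values.
#' * `wrongly_evaluated`: with probability `intensity`, replaces the value
#'   with an implausible one (scaled far off the growth median for
#'   anthropometry, shifted out of the plausible range for vitals and
#'   temperature), inflating extreme z-scores or the facility mean.
#'
#' @param pattern_type One of the four types above.
#' @param intensity Non-negative effect size; 0 means no behaviour.
#' @param target_values Values receiving spike mass (repeaters only):
#'   exactly 1 for `mono_repeater`, 2-3 for `multi_repeater`.
#' @return A `behavior_spec` object.
#' @export
behavior_spec <- function(pattern_type, intensity, target_values = NULL) {
  pattern_type <- match.arg(pattern_type,
                            c("skipper", "mono_repeater", "multi_repeater",
                              "wrongly_evaluated"))
  stopifnot(is.numeric(intensity), length(intensity) == 1L, intensity >= 0)
  if (pattern_type == "mono_repeater" && length(target_values) != 1L) {
    stop("mono_repeater requires exactly 1 target value", call. = FALSE)
  }
  if (pattern_type == "multi_repeater" &&
      !(length(target_values) %in% 2:3)) {
    stop("multi_repeater requires 2-3 target values", call. = FALSE)
  }
  structure(list(pattern_type = pattern_type, intensity = intensity,
                 target_values = target_values),
            class = "behavior_spec")
}

#' Inject a behaviour into one facility-sign pair
#'
#' Modifies only the targeted facility's records for the targeted sign;
#' all other records are returned bit-identical. Each eligible record draws
#' one uniform deviate and is affected iff it falls below `intensity`, so
#' at a fixed seed the distortion is monotone in intensity.
#'
#' @param records Consultation tibble.
#' @param hc_id,sign_id The targeted facility and sign.
#' @param behavior A [behavior_spec()].
#' @param seed Integer seed for the injection draws.
#' @param sign_specs Sign specifications (for recording precision and
#'   plausibility geometry); defaults to the package defaults.
#' @return The modified consultation tibble.
#' @export
inject_behavior <- function(records, hc_id, sign_id, behavior,
                            seed, sign_specs = default_sign_specs()) {
  stopifnot(inherits(behavior, "behavior_spec"))
  if (!sign_id %in% SIGN_IDS) {
    stop("unknown sign_id: ", sign_id, call. = FALSE)
  }
  if (behavior$intensity == 0) return(records)
  spec <- sign_specs[[sign_id]]
  st_col <- paste0(sign_id, "_status")
  v_col <- paste0(sign_id, "_value")
  in_fac <- records$hc_id == hc_id
  status <- records[[st_col]]

  if (behavior$pattern_type == "skipper") {
    # raise the not-feasible fraction among eligible records by `intensity`
    eligible <- in_fac & status != "not_applicable"
    p0 <- mean(status[eligible] == "not_feasible")
    q <- behavior$intensity / max(1 - p0, .Machine$double.eps)
    if (q > 1) {
      warning("skipper intensity exceeds attainable missing mass; clipped",
              call. = FALSE)
      q <- 1
    }
    flip <- which(eligible & status != "not_feasible")
    u <- with_seed(seed, stats::runif(length(flip)))
    hit <- flip[u < q]
    records[[st_col]][hit] <- "not_feasible"
    records[[v_col]][hit] <- NA_real_
    return(records)
  }

  measured <- which(in_fac & status == "measured")
  if (length(measured) == 0L) return(records)
  intensity <- behavior$intensity
  if (intensity > 1) {
    warning("intensity exceeds attainable mass; clipped to 1", call. = FALSE)
    intensity <- 1
  }

  if (behavior$pattern_type %in% c("mono_repeater", "multi_repeater")) {
    # add spike mass `intensity` on the targets: replacements are drawn
    # from non-target records only, so the targets' combined frequency
    # rises by `intensity` in expectation
    targets <- quantize(behavior$target_values, spec$precision)
    v <- records[[v_col]][measured]
    is_target <- v %in% targets
    m0 <- mean(is_target)
    q <- intensity / max(1 - m0, .Machine$double.eps)
    if (q > 1) {
      warning("repeater intensity exceeds attainable spike mass; clipped",
              call. = FALSE)
      q <- 1
    }
    draws <- with_seed(seed, list(
      u = stats::runif(length(measured)),
      pick = sample.int(length(targets), length(measured), replace = TRUE)))
    hit <- !is_target & draws$u < q
    records[[v_col]][measured[hit]] <- targets[draws$pick[hit]]
    return(records)
  }

  # wrongly_evaluated: push values implausibly low/high
  v <- records[[v_col]][measured]
  draws <- with_seed(seed, list(
    u = stats::runif(length(measured)),
    side = stats::runif(length(measured)) < 0.5,
    f = stats::runif(length(measured))))
  hit <- draws$u < intensity
  corrupted <- corrupt_values(sign_id, v, draws$side, draws$f)
  records[[v_col]][measured[hit]] <-
    quantize(corrupted[hit], spec$precision)
  records
}

# implausible replacement values per sign: anthropometry scaled far from
# the child's own value (drives |z| well past 2); vitals/temperature drawn
# beyond any plausible mean range
corrupt_values <- function(sign_id, v, side, f) {
  switch(sign_id,
    weight = ,
    muac = ,
    height = v * ifelse(side, 0.50 + 0.12 * f, 1.60 + 0.25 * f),
    temperature = 40.8 + 1.5 * f,
    heart_rate = ifelse(side, 30 + 10 * f, 210 + 30 * f),
    resp_rate = ifelse(side, 6 + 4 * f, 80 + 20 * f),
    spo2 = 55 + 15 * f)
}
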