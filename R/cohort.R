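#' Default multi-facility cohort configuration
#'
#' The study conditions the simulator emulates: 16 primary health centres,
#' roughly 1,255 consultations each (about 20,000 in total), children aged
#' 1 day to 14 years with sex drawn Bernoulli(0.5), and around a third of
#' consultations presenting with a respiratory main complaint (which gates
#' heart rate, respiratory rate and SpO2).
#'
#' @param n_facilities Number of health centres.
#' @param n_per_facility Consultations per centre.
#' @param p_respiratory Probability of a respiratory main complaint.
#' @param p_under5 Probability that a child is under five (ages are uniform
#'   within the under-five and five-to-fourteen strata; outpatient
#'   paediatric caseloads skew young).
#' @param sign_specs Named list of [sign_spec()]s.
#' @param behaviors List of behaviour assignments, each a list with
#'   `hc_id`, `sign_id` and a [behavior_spec()] under `behavior`.
#' @return A cohort config list consumed by [generate_cohort()].
#' @export
cohort_config <- function(n_facilities = 16,
                          n_per_facility = 1255,
                          p_respiratory = 0.35,
                          p_under5 = 0.6,
                          sign_specs = default_sign_specs(),
                          behaviors = list()) {
  facilities <- sprintf("HC-%02d", seq_len(n_facilities))
  stopifnot(n_per_facility >= 1)
  for (b in behaviors) {
    if (!b$hc_id %in% facilities) {
      stop("behavior references unknown facility: ", b$hc_id, call. = FALSE)
    }
    if (!b$sign_id %in% names(sign_specs)) {
      stop("behavior references unknown sign: ", b$sign_id, call. = FALSE)
    }
  }
  list(facilities = facilities, n_per_facility = n_per_facility,
       p_respiratory = p_respiratory, p_under5 = p_under5,
       sign_specs = sign_specs, behaviors = behaviors)
}

#' Read a cohort configuration from YAML
#'
#' Recognised top-level keys: `n_facilities`, `n_per_facility`,
#' `p_respiratory`, `p_under5` and a `behaviors:` list whose entries carry
#' `hc`, `sign`, `type`, `intensity` and optional `targets`. Sign
#' specifications stay at their package defaults; the YAML configures the
#' cohort shape and the injected behaviours.
#'
#' @param path YAML file.
#' @return A cohort config list.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  behaviors <- purrr::map(y$behaviors %||% list(), function(b) {
    list(hc_id = b$hc, sign_id = b$sign,
         behavior = behavior_spec(b$type, b$intensity,
                                  target_values = unlist(b$targets)))
  })
  cohort_config(
    n_facilities = y$n_facilities %||% 16,
    n_per_facility = y$n_per_facility %||% 1255,
    p_respiratory = y$p_respiratory %||% 0.35,
    p_under5 = y$p_under5 %||% 0.6,
    behaviors = behaviors)
}

#' Generate a synthetic consultation cohort
#'
#' Draws one row per consultation with facility id, age, sex, respiratory
#' complaint flag and, per sign, a status in `measured`, `not_feasible`,
#' `estimated` (weight only) or `not_applicable` (ineligible), plus a value
#' on the sign's recording grid when measured. Behaviours listed in the
#' config are then injected via [inject_behavior()] with seeds derived from
#' the master seed, so the whole cohort is a deterministic function of
#' `(config, seed)`.
#'
#' @param config A [cohort_config()] list.
#' @param seed Integer master seed.
#' @return Tibble of consultations (one row each).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  records <- with_seed(seed, generate_baseline(config))
  if (length(config$behaviors) > 0L) {
    seeds <- derive_seeds(seed, length(config$behaviors))
    for (i in seq_along(config$behaviors)) {
      b <- config$behaviors[[i]]
      records <- inject_behavior(records, b$hc_id, b$sign_id, b$behavior,
                                 seed = seeds[i])
    }
  }
  records
}

generate_baseline <- function(config) {
  n_fac <- length(config$facilities)
  n <- config$n_per_facility * n_fac
  hc_id <- rep(config$facilities, each = config$n_per_facility)
  under5 <- stats::runif(n) < config$p_under5
  age_days <- ifelse(under5,
                     sample.int(1825L, n, replace = TRUE),
                     1825L + sample.int(5110L - 1825L, n, replace = TRUE))
  records <- tibble::tibble(
    consultation_id = sprintf("C%06d", seq_len(n)),
    hc_id = hc_id,
    age_days = as.integer(age_days),
    sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
    respiratory_complaint = stats::runif(n) < config$p_respiratory)
  for (nm in names(config$sign_specs)) {
    spec <- config$sign_specs[[nm]]
    records <- draw_sign(records, spec)
  }
  records
}

# truncated-normal draw by inverse CDF (vectorised, exact)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

draw_sign <- function(records, spec) {
  n <- nrow(records)
  eligible <- sign_eligible(spec, records$age_days,
                            records$respiratory_complaint)
  status <- rep("not_applicable", n)
  value <- rep(NA_real_, n)
  n_el <- sum(eligible)
  if (n_el > 0L) {
    u <- stats::runif(n_el)
    st <- rep("measured", n_el)
    st[u < spec$not_feasible_rate] <- "not_feasible"
    if (spec$estimated_rate > 0) {
      st[u >= spec$not_feasible_rate &
           u < spec$not_feasible_rate + spec$estimated_rate] <- "estimated"
    }
    raw <- draw_values(spec, records$age_days[eligible],
                       records$sex[eligible])
    v <- rep(NA_real_, n_el)
    v[st == "measured"] <- quantize(raw[st == "measured"], spec$precision)
    status[eligible] <- st
    value[eligible] <- v
  }
  records[[paste0(spec$sign_id, "_status")]] <- status
  records[[paste0(spec$sign_id, "_value")]] <- value
  records
}

draw_values <- function(spec, age_days, sex) {
  n <- length(age_days)
  d <- spec$dist
  if (d$type == "normal") {
    rtruncnorm(n, d$mean, d$sd, d$lower, d$upper)
  } else {
    med <- growth_median(d$indicator, age_days, sex)
    med * exp(d$sigma * stats::rnorm(n))
  }
}

#' Write / read a consultations CSV
#'
#' One row per consultation; per-sign `<sign>_status` and `<sign>_value`
#' columns, UTF-8, "." decimal separator, header row mandatory. Any
#' z-score columns present are carried along.
#'
#' @param records Consultation tibble.
#' @param path Output CSV path.
#' @return `write_consultations()` returns `path` invisibly;
#'   `read_consultations()` returns the tibble.
#' @export
write_consultations <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_consultations
#' @export
read_consultations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
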