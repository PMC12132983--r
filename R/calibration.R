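#' Null-calibration experiment
#'
#' Generates behaviour-free cohorts (every facility drawn from identical
#' baseline settings) and counts how many facility-sign/indicator pairs
#' the classifier leaves unflagged. With a well-calibrated threshold
#' configuration and large per-facility samples, sampling noise alone
#' should essentially never reach the mild band.
#'
#' @param n_seeds Number of independent cohorts.
#' @param n_facilities,n_per_facility Cohort shape.
#' @param seed Master seed; cohort seeds are derived from it.
#' @param config Threshold configuration.
#' @return List: `flag_free_rate` (share of classifiable facility-pair
#'   cells without a flag, pooled over cohorts), `n_pairs`, `n_flagged`,
#'   and the per-cohort flag counts.
#' @export
null_calibration <- function(n_seeds = 20, n_facilities = 16,
                             n_per_facility = 20000, seed = 1,
                             config = threshold_config()) {
  cfg <- cohort_config(n_facilities = n_facilities,
                       n_per_facility = n_per_facility)
  ref <- load_growth_reference()
  seeds <- derive_seeds(seed, n_seeds)
  applic <- applicability_matrix()
  classifiable <- names(Filter(function(x) length(x) > 0, applic))
  flags_per_cohort <- integer(n_seeds)
  n_pairs <- 0L
  for (i in seq_len(n_seeds)) {
    rec <- generate_cohort(cfg, seeds[i])
    rec <- add_zscores(rec, ref)
    s <- summarize_cohort(rec)
    fl <- suppressMessages(classify_cohort(s, config, applic))
    flags_per_cohort[i] <- length(unique(paste(fl$hc_id, fl$sign)))
    n_pairs <- n_pairs + n_facilities * length(classifiable)
  }
  n_flagged <- sum(flags_per_cohort)
  list(flag_free_rate = 1 - n_flagged / n_pairs,
       n_pairs = n_pairs, n_flagged = n_flagged,
       flags_per_cohort = flags_per_cohort)
}

#' Rotation of injection-recovery cases
#'
#' The (sign, pattern type, severity band) combinations exercised by
#' [run_injection_recovery()], with intensities at severity band centres
#' (mild 0.075, moderate 0.20; the severe band is open-ended and uses
#' 0.45). Repeater targets are the sign's most frequent baseline values —
#' heaping lands on common values, and the top-k excess statistics only
#' respond when spike mass aligns with the recorded mode.
#'
#' @return Tibble of cases, one per (sign, type, band).
#' @export
recovery_cases <- function() {
  intensities <- c(mild = 0.075, moderate = 0.20, severe = 0.45)
  base <- dplyr::bind_rows(
    tibble::tibble(sign = "height", type = "skipper"),
    tibble::tibble(sign = "resp_rate", type = "skipper"),
    tibble::tibble(sign = "temperature", type = "mono_repeater"),
    tibble::tibble(sign = "spo2", type = "mono_repeater"),
    tibble::tibble(sign = "temperature", type = "multi_repeater"),
    tibble::tibble(sign = "resp_rate", type = "multi_repeater"),
    tibble::tibble(sign = "weight", type = "wrongly_evaluated"))
  cases <- tidyr::crossing(base, band = names(intensities))
  cases$intensity <- intensities[cases$band]
  cases$targets <- purrr::map2(cases$sign, cases$type, function(s, ty) {
    if (ty == "mono_repeater") baseline_top_values(s, 1)
    else if (ty == "multi_repeater") baseline_top_values(s, 3)
    else NULL
  })
  cases
}

# most frequent values of a sign's baseline distribution on its grid
baseline_top_values <- function(sign_id, k) {
  spec <- default_sign_specs()[[sign_id]]
  d <- spec$dist
  stopifnot(d$type == "normal")
  grid <- quantize(seq(d$lower, d$upper, by = spec$precision),
                   spec$precision)
  lo <- stats::pnorm(grid - spec$precision / 2, d$mean, d$sd)
  hi <- stats::pnorm(pmin(grid + spec$precision / 2, d$upper),
                     d$mean, d$sd)
  grid[order(hi - lo, decreasing = TRUE)][seq_len(k)]
}

#' Injection-recovery experiment
#'
#' Each run generates a behaviour-free multi-facility cohort, injects one
#' behaviour at one facility-sign pair (cycling through
#' [recovery_cases()]), classifies, and records whether the injected
#' (sign, pattern type) was recovered and whether the recovered severity
#' matches the injected band. Flags on z-indicators are mapped back to
#' their source sign, so a corrupted weight recovered through
#' weight-for-age counts as recovered.
#'
#' @param n_runs Number of seeded runs.
#' @param n_facilities,n_per_facility Cohort shape.
#' @param seed Master seed.
#' @param config Threshold configuration.
#' @return Tibble with one row per run: injected case, `recovered_type`
#'   and `recovered_band` logicals.
#' @export
run_injection_recovery <- function(n_runs = 50, n_facilities = 16,
                                   n_per_facility = 2000, seed = 1,
                                   config = threshold_config()) {
  cases <- recovery_cases()
  ref <- load_growth_reference()
  seeds <- derive_seeds(seed, 2L * n_runs)
  applic <- applicability_matrix()
  out <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    case <- cases[((i - 1L) %% nrow(cases)) + 1L, ]
    cfg <- cohort_config(n_facilities = n_facilities,
                         n_per_facility = n_per_facility)
    rec <- generate_cohort(cfg, seeds[i])
    target_hc <- cfg$facilities[((i - 1L) %% n_facilities) + 1L]
    beh <- behavior_spec(case$type, case$intensity,
                         target_values = case$targets[[1]])
    rec <- inject_behavior(rec, target_hc, case$sign, beh,
                           seed = seeds[n_runs + i])
    rec <- add_zscores(rec, ref)
    s <- summarize_cohort(rec)
    fl <- suppressMessages(classify_cohort(s, config, applic))
    hit <- fl[fl$hc_id == target_hc &
                flag_source_sign(fl$sign) == case$sign &
                fl$pattern_type == case$type, ]
    out[[i]] <- tibble::tibble(
      run = i, sign = case$sign, type = case$type, band = case$band,
      intensity = case$intensity,
      recovered_type = nrow(hit) > 0L,
      recovered_band = nrow(hit) > 0L && any(hit$severity == case$band))
  }
  dplyr::bind_rows(out)
}
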