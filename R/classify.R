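#' Threshold configuration for pattern classification
#'
#' Severity bands on the deviation of a facility's statistic from the
#' pooled reference. Excess fractions (missing, top-value frequency,
#' extreme z-scores) are absolute percentage-point differences: 5-10
#' points is mild, 10-30 moderate, above 30 severe. IQR shrinkage is
#' measured relative to the facility's own IQR,
#' `(reference_iqr - facility_iqr) / facility_iqr`: 25-50% mild, 50-100%
#' moderate, above 100% (facility IQR under half the reference) severe.
#' Plausible ranges bound the facility mean for the implausible-mean route
#' of the wrongly-evaluated pattern.
#'
#' @param skipper_bands,repeater_freq_bands,wrong_z_bands Named numeric
#'   vectors `c(mild =, moderate =, severe =)` of lower band edges on
#'   excess fractions.
#' @param iqr_shrink_bands Lower band edges on the IQR shrinkage ratio.
#' @param plausible_ranges Named list of `c(lo, hi)` plausible mean ranges
#'   per sign.
#' @param excess_scale `"absolute"` (percentage-point difference of
#'   fractions, the default reading) or `"relative"` (ratio excess,
#'   `facility/reference - 1`).
#' @return A `threshold_config` object.
#' @export
threshold_config <- function(
    skipper_bands = c(mild = 0.05, moderate = 0.10, severe = 0.30),
    repeater_freq_bands = c(mild = 0.05, moderate = 0.10, severe = 0.30),
    iqr_shrink_bands = c(mild = 0.25, moderate = 0.50, severe = 1.00),
    wrong_z_bands = c(mild = 0.05, moderate = 0.10, severe = 0.30),
    plausible_ranges = list(
      temperature = c(35.5, 38.0),
      muac = c(11, 18),
      heart_rate = c(80, 160),
      resp_rate = c(20, 50),
      spo2 = c(92, 100)),
    excess_scale = c("absolute", "relative")) {
  excess_scale <- match.arg(excess_scale)
  for (b in list(skipper_bands, repeater_freq_bands, iqr_shrink_bands,
                 wrong_z_bands)) {
    if (!identical(names(b), c("mild", "moderate", "severe")) ||
        any(diff(b) <= 0)) {
      stop("bands must be named mild/moderate/severe and increasing",
           call. = FALSE)
    }
  }
  structure(list(skipper_bands = skipper_bands,
                 repeater_freq_bands = repeater_freq_bands,
                 iqr_shrink_bands = iqr_shrink_bands,
                 wrong_z_bands = wrong_z_bands,
                 plausible_ranges = plausible_ranges,
                 excess_scale = excess_scale),
            class = "threshold_config")
}

#' Read a threshold configuration from YAML
#'
#' Keys mirror the [threshold_config()] arguments; omitted keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `threshold_config` object.
#' @export
read_threshold_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_band <- function(x, default) {
    if (is.null(x)) return(default)
    unlist(x)[c("mild", "moderate", "severe")]
  }
  d <- threshold_config()
  threshold_config(
    skipper_bands = as_band(y$skipper_bands, d$skipper_bands),
    repeater_freq_bands = as_band(y$repeater_freq_bands,
                                  d$repeater_freq_bands),
    iqr_shrink_bands = as_band(y$iqr_shrink_bands, d$iqr_shrink_bands),
    wrong_z_bands = as_band(y$wrong_z_bands, d$wrong_z_bands),
    plausible_ranges = if (is.null(y$plausible_ranges)) d$plausible_ranges
      else lapply(y$plausible_ranges, unlist),
    excess_scale = y$excess_scale %||% d$excess_scale)
}

#' Which pattern types apply to which signs
#'
#' Skipper does not apply to temperature, weight and z-scores (their
#' missingness is not informative there); mono- and multi-repeater do not
#' apply to weight, height and z-scores; wrongly-evaluated does not apply
#' to raw weight and height (their errors surface through the z-scores).
#'
#' @return Named list mapping each sign or indicator to its allowed
#'   pattern types.
#' @export
applicability_matrix <- function() {
  all_types <- c("skipper", "mono_repeater", "multi_repeater",
                 "wrongly_evaluated")
  out <- list(
    temperature = setdiff(all_types, "skipper"),
    muac = all_types,
    weight = character(0),
    height = "skipper",
    heart_rate = all_types,
    resp_rate = all_types,
    spo2 = all_types)
  for (ind in Z_INDICATORS) out[[ind]] <- "wrongly_evaluated"
  out
}

# map an excess statistic to a severity through lower band edges:
# [mild, moderate) mild, [moderate, severe] moderate, > severe severe
band_severity <- function(x, bands) {
  if (is.na(x) || x < bands[["mild"]]) return(NA_character_)
  if (x > bands[["severe"]]) return("severe")
  if (x >= bands[["moderate"]]) return("moderate")
  "mild"
}

excess_of <- function(hc_stat, ref_stat, config) {
  if (config$excess_scale == "absolute") hc_stat - ref_stat
  else if (is.na(ref_stat) || ref_stat == 0) NA_real_
  else hc_stat / ref_stat - 1
}

new_flag <- function(hc_id, sign, pattern_type, severity, evidence) {
  tibble::tibble(hc_id = hc_id, sign = sign, pattern_type = pattern_type,
                 severity = severity,
                 evidence = as.character(
                   jsonlite::toJSON(evidence, auto_unbox = TRUE,
                                    digits = 6)))
}

empty_flags <- function() {
  tibble::tibble(hc_id = character(), sign = character(),
                 pattern_type = character(), severity = character(),
                 evidence = character())
}

#' Flag a facility-sign pair as a skipper
#'
#' Compares the facility's missing fraction with the pooled reference; the
#' excess is mapped through the skipper severity bands.
#'
#' @param summary,reference One-row summary tibbles for the same sign
#'   (facility and pooled `"ALL"`).
#' @param config A [threshold_config()].
#' @return One-row flag tibble, or `NULL` if no band is reached.
#' @export
classify_skipper <- function(summary, reference, config = threshold_config()) {
  excess <- excess_of(summary$missing_frac, reference$missing_frac, config)
  sev <- band_severity(excess, config$skipper_bands)
  if (is.na(sev)) return(NULL)
  new_flag(summary$hc_id, summary$sign, "skipper", sev,
           list(missing_frac = summary$missing_frac,
                reference_missing_frac = reference$missing_frac,
                excess = excess))
}

#' Flag a facility-sign pair as a mono- or multi-repeater
#'
#' Mono candidate when the excess modal frequency reaches a band; multi
#' candidate when the excess top-3 cumulative frequency reaches a band.
#' When both qualify, mono takes precedence unless the multi criterion
#' reaches a strictly higher severity band (concentration on 2-3 values
#' always lifts the modal frequency a little, so a weak mono band must not
#' mask a strong multi band). The IQR-shrinkage criterion is combined by
#' OR, with final severity the maximum of the frequency and IQR criteria;
#' a facility IQR of zero against a positive reference IQR counts as
#' severe shrinkage. When only the IQR criterion reaches a band the flag
#' is typed mono-repeater (variance collapse around a single value).
#'
#' @inheritParams classify_skipper
#' @return One-row flag tibble or `NULL`.
#' @export
classify_repeater <- function(summary, reference,
                              config = threshold_config()) {
  excess_modal <- excess_of(summary$modal_frac, reference$modal_frac, config)
  excess_top3 <- excess_of(summary$top3_cum_frac, reference$top3_cum_frac,
                           config)
  sev_mono <- band_severity(excess_modal, config$repeater_freq_bands)
  sev_multi <- band_severity(excess_top3, config$repeater_freq_bands)
  shrink <- if (is.na(summary$iqr) || is.na(reference$iqr)) NA_real_
    else if (summary$iqr == 0 && reference$iqr > 0) Inf
    else if (summary$iqr == 0) NA_real_
    else (reference$iqr - summary$iqr) / summary$iqr
  sev_iqr <- if (is.na(shrink)) NA_character_
    else if (is.infinite(shrink)) "severe"
    else band_severity(shrink, config$iqr_shrink_bands)
  if (is.na(sev_mono) && is.na(sev_multi) && is.na(sev_iqr)) return(NULL)
  rank_mono <- match(sev_mono, severity_levels, nomatch = 0L)
  rank_multi <- match(sev_multi, severity_levels, nomatch = 0L)
  type <- if (rank_mono == 0L && rank_multi == 0L) "mono_repeater"
    else if (rank_mono >= rank_multi) "mono_repeater"
    else "multi_repeater"
  sev_freq <- if (type == "mono_repeater") sev_mono else sev_multi
  new_flag(summary$hc_id, summary$sign, type,
           severity_max(sev_freq, sev_iqr),
           list(modal_frac = summary$modal_frac,
                reference_modal_frac = reference$modal_frac,
                top3_cum_frac = summary$top3_cum_frac,
                reference_top3_cum_frac = reference$top3_cum_frac,
                iqr = summary$iqr, reference_iqr = reference$iqr,
                iqr_shrinkage = shrink,
                mono_also_qualifies = !is.na(sev_mono) && !is.na(sev_multi)))
}

#' Flag a facility-sign pair as wrongly evaluated
#'
#' For z-indicators: the excess extreme-z fraction (share of raw z below
#' -2 or above 2) against the reference, mapped through the wrongly-
#' evaluated bands. For temperature and vitals: a facility mean outside
#' the sign's plausible range yields a mild flag (the implausible-mean
#' route has no graded counterpart).
#'
#' @inheritParams classify_skipper
#' @return One-row flag tibble or `NULL`.
#' @export
classify_wrongly_evaluated <- function(summary, reference,
                                       config = threshold_config()) {
  sign <- summary$sign
  if (sign %in% Z_INDICATORS) {
    excess <- excess_of(summary$extreme_z_frac, reference$extreme_z_frac,
                        config)
    sev <- band_severity(excess, config$wrong_z_bands)
    if (is.na(sev)) return(NULL)
    return(new_flag(summary$hc_id, sign, "wrongly_evaluated", sev,
                    list(extreme_z_frac = summary$extreme_z_frac,
                         reference_extreme_z_frac = reference$extreme_z_frac,
                         excess = excess)))
  }
  rng <- config$plausible_ranges[[sign]]
  if (is.null(rng)) {
    stop("no plausible range configured for sign '", sign, "'",
         call. = FALSE)
  }
  if (is.na(summary$mean) || (summary$mean >= rng[1] &&
                              summary$mean <= rng[2])) {
    return(NULL)
  }
  new_flag(summary$hc_id, sign, "wrongly_evaluated", "mild",
           list(mean = summary$mean, plausible_lo = rng[1],
                plausible_hi = rng[2]))
}

#' Classify every sign of one facility
#'
#' Applies the three classifiers to each sign and indicator allowed by the
#' applicability matrix; a sign may carry several flags (e.g. skipper and
#' mono-repeater). Facility-sign pairs with insufficient measured data are
#' skipped with a notice.
#'
#' @param summaries Summary rows for one facility.
#' @param references Pooled `"ALL"` rows covering the same signs.
#' @param config A [threshold_config()].
#' @param applicability An [applicability_matrix()].
#' @return Flag tibble (possibly zero rows).
#' @export
classify_facility <- function(summaries, references,
                              config = threshold_config(),
                              applicability = applicability_matrix()) {
  flags <- list()
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    allowed <- applicability[[s$sign]]
    if (is.null(allowed) || length(allowed) == 0L) next
    r <- references[references$sign == s$sign, ]
    if (nrow(r) != 1L) {
      stop("missing pooled reference for sign '", s$sign, "'",
           call. = FALSE)
    }
    if (!isTRUE(s$sufficient_n)) {
      rlang::inform(paste0("skipping ", s$hc_id, " / ", s$sign,
                           ": insufficient data (n_measured = ",
                           s$n_measured, ")"),
                    class = "signgaps_insufficient_data")
      next
    }
    if ("skipper" %in% allowed) {
      flags[[length(flags) + 1L]] <- classify_skipper(s, r, config)
    }
    if (any(c("mono_repeater", "multi_repeater") %in% allowed)) {
      flags[[length(flags) + 1L]] <- classify_repeater(s, r, config)
    }
    if ("wrongly_evaluated" %in% allowed) {
      flags[[length(flags) + 1L]] <- classify_wrongly_evaluated(s, r, config)
    }
  }
  flags <- purrr::compact(flags)
  if (length(flags) == 0L) return(empty_flags())
  dplyr::bind_rows(flags)
}

#' Classify every facility in a summary table
#'
#' @param summaries Output of [summarize_cohort()] including the `"ALL"`
#'   reference rows.
#' @inheritParams classify_facility
#' @return Flag tibble over all facilities.
#' @export
classify_cohort <- function(summaries, config = threshold_config(),
                            applicability = applicability_matrix()) {
  refs <- summaries[summaries$hc_id == "ALL", ]
  hcs <- setdiff(unique(summaries$hc_id), "ALL")
  dplyr::bind_rows(purrr::map(hcs, function(hc) {
    classify_facility(summaries[summaries$hc_id == hc, ], refs,
                      config, applicability)
  })) |>
    (\(x) if (nrow(x) == 0L) empty_flags() else x)()
}

#' Select facilities for prospective observation
#'
#' A facility is selected when it has at least two distinct flagged signs
#' and at least one flag of moderate or severe level.
#'
#' @param flags Flag tibble from [classify_cohort()].
#' @return Character vector of selected facility ids (sorted).
#' @export
select_health_centers <- function(flags) {
  if (nrow(flags) == 0L) return(character(0))
  sel <- flags |>
    dplyr::group_by(.data$hc_id) |>
    dplyr::summarise(
      n_signs = dplyr::n_distinct(.data$sign),
      any_mod = any(.data$severity %in% c("moderate", "severe")),
      .groups = "drop") |>
    dplyr::filter(.data$n_signs >= 2, .data$any_mod)
  sort(sel$hc_id)
}

#' Source sign of a flag
#'
#' Maps a flagged z-indicator back to the measured sign it derives from
#' (e.g. `weight_for_age` to `weight`); raw signs map to themselves.
#'
#' @param sign_or_indicator Character vector of signs / indicators.
#' @return Character vector of source signs.
#' @export
flag_source_sign <- function(sign_or_indicator) {
  ifelse(sign_or_indicator %in% names(Z_SOURCE_SIGN),
         unname(Z_SOURCE_SIGN[sign_or_indicator]),
         sign_or_indicator)
}

#' Write / read a flags CSV
#'
#' @param flags Flag tibble.
#' @param path CSV path (evidence stays a JSON string column).
#' @return `write_flags()` returns `path` invisibly; `read_flags()` the
#'   tibble.
#' @export
write_flags <- function(flags, path) {
  readr::write_csv(flags, path)
  invisible(path)
}

#' @rdname write_flags
#' @export
read_flags <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
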