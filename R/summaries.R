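#' Per-facility, per-sign summary statistics
#'
#' Computes the statistical parameters the facility comparison runs on:
#' the missing fraction (not-feasible plus estimated over eligible), the
#' modal value and its frequency, the top-3 value frequencies, mean,
#' median and IQR of measured values. Quantiles use linear interpolation
#' between order statistics (`stats::quantile(type = 7)`); modal ties are
#' broken by the smallest value. Facility-sign pairs with fewer than
#' `min_n` measured values are marked `sufficient_n = FALSE` and are not
#' classifiable.
#'
#' @param records Consultation tibble.
#' @param hc_id One facility id, or `"ALL"` for the pooled reference over
#'   every facility (the facility under test included).
#' @param sign_id One of `SIGN_IDS`.
#' @param min_n Minimum measured count for a classifiable summary.
#' @return One-row tibble (a `SignSummary`).
#' @export
summarize_sign <- function(records, hc_id, sign_id, min_n = 20L) {
  sign_id <- match.arg(sign_id, SIGN_IDS)
  sub <- if (identical(hc_id, "ALL")) records else
    records[records$hc_id == hc_id, ]
  status <- sub[[paste0(sign_id, "_status")]]
  value <- sub[[paste0(sign_id, "_value")]]
  eligible <- status != "not_applicable"
  n_eligible <- sum(eligible)
  if (n_eligible == 0L) {
    return(empty_summary(hc_id, sign_id))
  }
  measured <- eligible & status == "measured"
  v <- value[measured]
  n_measured <- length(v)
  missing_frac <- 1 - n_measured / n_eligible
  if (n_measured == 0L) {
    out <- empty_summary(hc_id, sign_id)
    out$n_eligible <- n_eligible
    out$missing_frac <- missing_frac
    return(out)
  }
  top <- value_frequencies(v)
  tibble::tibble(
    hc_id = hc_id, sign = sign_id,
    n_eligible = n_eligible, n_measured = n_measured,
    missing_frac = missing_frac,
    modal_value = top$value[1], modal_frac = top$frac[1],
    top3 = serialize_top3(top),
    top3_cum_frac = sum(top$frac[seq_len(min(3L, nrow(top)))]),
    mean = mean(v),
    median = unname(stats::quantile(v, 0.5, type = 7)),
    iqr = unname(stats::quantile(v, 0.75, type = 7) -
                   stats::quantile(v, 0.25, type = 7)),
    extreme_z_frac = NA_real_,
    sufficient_n = n_measured >= min_n)
}

empty_summary <- function(hc_id, sign_id) {
  tibble::tibble(
    hc_id = hc_id, sign = sign_id,
    n_eligible = 0L, n_measured = 0L,
    missing_frac = NA_real_, modal_value = NA_real_, modal_frac = NA_real_,
    top3 = NA_character_, top3_cum_frac = NA_real_,
    mean = NA_real_, median = NA_real_, iqr = NA_real_,
    extreme_z_frac = NA_real_, sufficient_n = FALSE)
}

# frequency table sorted by descending frequency, ties to smallest value
value_frequencies <- function(v) {
  tab <- table(v)
  vals <- as.numeric(names(tab))
  fr <- as.numeric(tab) / length(v)
  ord <- order(-fr, vals)
  tibble::tibble(value = vals[ord], frac = fr[ord])
}

serialize_top3 <- function(top) {
  k <- seq_len(min(3L, nrow(top)))
  paste(sprintf("%g:%.6g", top$value[k], top$frac[k]), collapse = ";")
}

#' Summarise a growth z-score indicator for one facility
#'
#' The extreme-value fraction is the share of raw z-scores below -2 or
#' above 2 among computable records (children aged 2 months to 5 years
#' with a measured source sign). Modal statistics are reported on the
#' clamped integer z-scores the tool displays.
#'
#' @param records Consultation tibble with z-score columns
#'   (see [add_zscores()]).
#' @param hc_id Facility id or `"ALL"`.
#' @param indicator One of `Z_INDICATORS`.
#' @param min_n Minimum computable count for a classifiable summary.
#' @return One-row tibble (a `SignSummary` for the indicator).
#' @export
summarize_zscores <- function(records, hc_id, indicator, min_n = 20L) {
  indicator <- match.arg(indicator, Z_INDICATORS)
  sub <- if (identical(hc_id, "ALL")) records else
    records[records$hc_id == hc_id, ]
  age_ok <- sub$age_days >= Z_AGE_MIN_DAYS & sub$age_days <= Z_AGE_MAX_DAYS
  n_eligible <- sum(age_ok)
  raw <- sub[[paste0(indicator, "_z_raw")]][age_ok]
  clamped <- sub[[paste0(indicator, "_z")]][age_ok]
  ok <- !is.na(raw)
  n_measured <- sum(ok)
  if (n_eligible == 0L || n_measured == 0L) {
    out <- empty_summary(hc_id, indicator)
    out$n_eligible <- n_eligible
    if (n_eligible > 0L) out$missing_frac <- 1
    return(out)
  }
  top <- value_frequencies(clamped[ok])
  tibble::tibble(
    hc_id = hc_id, sign = indicator,
    n_eligible = n_eligible, n_measured = n_measured,
    missing_frac = 1 - n_measured / n_eligible,
    modal_value = top$value[1], modal_frac = top$frac[1],
    top3 = serialize_top3(top),
    top3_cum_frac = sum(top$frac[seq_len(min(3L, nrow(top)))]),
    mean = mean(raw[ok]),
    median = unname(stats::quantile(raw[ok], 0.5, type = 7)),
    iqr = unname(stats::quantile(raw[ok], 0.75, type = 7) -
                   stats::quantile(raw[ok], 0.25, type = 7)),
    extreme_z_frac = mean(raw[ok] < -2 | raw[ok] > 2),
    sufficient_n = n_measured >= min_n)
}

#' Pooled all-facility reference summary
#'
#' The comparison baseline: the same computation as [summarize_sign()] /
#' [summarize_zscores()] over the union of every facility's records
#' (`hc_id = "ALL"`), used in place of a gold standard.
#'
#' @param records Consultation tibble.
#' @param sign_or_indicator A sign id or z-indicator name.
#' @param min_n Minimum measured count.
#' @return One-row tibble.
#' @export
pooled_reference <- function(records, sign_or_indicator, min_n = 20L) {
  if (sign_or_indicator %in% Z_INDICATORS) {
    summarize_zscores(records, "ALL", sign_or_indicator, min_n)
  } else {
    summarize_sign(records, "ALL", sign_or_indicator, min_n)
  }
}

#' Summarise every facility-sign pair plus the pooled reference
#'
#' @param records Consultation tibble (with z-score columns if indicator
#'   summaries are wanted).
#' @param signs Signs to summarise (default all seven).
#' @param indicators Z-indicators to summarise (default all three when the
#'   z columns are present, none otherwise).
#' @param min_n Minimum measured count for classifiability.
#' @return Tibble of summaries, one row per (facility-or-ALL, sign).
#' @export
summarize_cohort <- function(records, signs = SIGN_IDS,
                             indicators = NULL, min_n = 20L) {
  if (is.null(indicators)) {
    has_z <- paste0(Z_INDICATORS, "_z_raw") %in% names(records)
    indicators <- Z_INDICATORS[has_z]
  }
  hcs <- c(sort(unique(records$hc_id)), "ALL")
  rows <- list()
  for (hc in hcs) {
    for (s in signs) {
      rows[[length(rows) + 1L]] <- summarize_sign(records, hc, s, min_n)
    }
    for (ind in indicators) {
      rows[[length(rows) + 1L]] <- summarize_zscores(records, hc, ind, min_n)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a summaries CSV
#'
#' Columns as in the summary tibbles; the top-3 list is serialized as
#' `value:frac;value:frac;value:frac`.
#'
#' @param summaries Summary tibble from [summarize_cohort()].
#' @param path CSV path.
#' @return `write_summaries()` returns `path` invisibly;
#'   `read_summaries()` the tibble.
#' @export
write_summaries <- function(summaries, path) {
  readr::write_csv(summaries, path)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
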