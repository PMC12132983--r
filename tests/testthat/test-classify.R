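ref_row <- function(sign = "resp_rate", ...) {
  mk_summary(hc_id = "ALL", sign = sign, ...)
}

test_that("skipper severities follow the excess-missing bands", {
  cfg <- threshold_config()
  r <- ref_row(missing_frac = 0.05)
  sev_at <- function(mf) {
    f <- classify_skipper(mk_summary(missing_frac = mf), r, cfg)
    if (is.null(f)) NA_character_ else f$severity
  }
  expect_equal(sev_at(0.40), "severe")    # excess 0.35 > 0.30
  expect_equal(sev_at(0.12), "mild")      # excess 0.07 in [0.05, 0.10)
  expect_equal(sev_at(0.05), NA_character_)
  expect_equal(sev_at(0.20), "moderate")  # excess 0.15
  expect_equal(sev_at(0.35), "moderate")  # excess 0.30 still moderate
  expect_equal(sev_at(0.351), "severe")
})

test_that("repeater combines frequency and IQR criteria", {
  cfg <- threshold_config()
  r <- ref_row(modal_frac = 0.20, top3_cum_frac = 0.35, iqr = 1.0)
  f <- classify_repeater(mk_summary(modal_frac = 0.60,
                                    top3_cum_frac = 0.65, iqr = 1.0), r, cfg)
  expect_equal(f$pattern_type, "mono_repeater")
  expect_equal(f$severity, "severe")  # excess modal 0.40 > 0.30

  expect_null(classify_repeater(
    mk_summary(modal_frac = 0.20, top3_cum_frac = 0.35, iqr = 1.0), r, cfg))

  # IQR-only route: shrinkage (1.0 - 0.4) / 0.4 = 1.5 > 1.00 is severe
  f2 <- classify_repeater(mk_summary(modal_frac = 0.20,
                                     top3_cum_frac = 0.35, iqr = 0.4),
                          r, cfg)
  expect_equal(f2$severity, "severe")

  # facility IQR of zero against a positive reference is severe shrinkage
  f3 <- classify_repeater(mk_summary(modal_frac = 0.2,
                                     top3_cum_frac = 0.35, iqr = 0),
                          r, cfg)
  expect_equal(f3$severity, "severe")

  # a strong 2-3-value spike outranks the incidental modal lift
  f4 <- classify_repeater(mk_summary(modal_frac = 0.27,
                                     top3_cum_frac = 0.70, iqr = 1.0),
                          r, cfg)
  expect_equal(f4$pattern_type, "multi_repeater")
  expect_equal(f4$severity, "severe")
})

test_that("wrongly-evaluated uses z-bands or the implausible-mean route", {
  cfg <- threshold_config(plausible_ranges = list(temperature = c(35, 40.5)))
  rz <- ref_row(sign = "weight_for_age", extreme_z_frac = 0.05)
  f <- classify_wrongly_evaluated(
    mk_summary(sign = "weight_for_age", extreme_z_frac = 0.40), rz, cfg)
  expect_equal(f$severity, "severe")  # excess 0.35
  expect_null(classify_wrongly_evaluated(
    mk_summary(sign = "weight_for_age", extreme_z_frac = 0.05), rz, cfg))

  rt <- ref_row(sign = "temperature", mean = 36.8)
  f2 <- classify_wrongly_evaluated(
    mk_summary(sign = "temperature", mean = 41.0), rt, cfg)
  expect_equal(f2$severity, "mild")
  expect_null(classify_wrongly_evaluated(
    mk_summary(sign = "temperature", mean = 36.9), rt, cfg))
  expect_error(classify_wrongly_evaluated(
    mk_summary(sign = "spo2", mean = 90), ref_row(sign = "spo2"), cfg),
    "no plausible range")
})

test_that("severity is monotone in the excess statistic", {
  cfg <- threshold_config()
  r <- ref_row(missing_frac = 0.05)
  ranks <- vapply(seq(0.05, 0.60, by = 0.01), function(mf) {
    f <- classify_skipper(mk_summary(missing_frac = mf), r, cfg)
    if (is.null(f)) 0L else match(f$severity, c("mild", "moderate", "severe"))
  }, integer(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("flags never violate the applicability matrix", {
  applic <- applicability_matrix()
  expect_identical(applic$weight, character(0))
  expect_identical(applic$height, "skipper")
  expect_false("skipper" %in% applic$temperature)
  expect_identical(applic$weight_for_age, "wrongly_evaluated")

  cfg <- cohort_config(
    n_facilities = 4, n_per_facility = 1500,
    behaviors = list(
      list(hc_id = "HC-01", sign_id = "resp_rate",
           behavior = behavior_spec("skipper", 0.4)),
      list(hc_id = "HC-02", sign_id = "temperature",
           behavior = behavior_spec("mono_repeater", 0.5, 36.8)),
      list(hc_id = "HC-03", sign_id = "weight",
           behavior = behavior_spec("wrongly_evaluated", 0.4))))
  rec <- add_zscores(generate_cohort(cfg, seed = 77))
  fl <- suppressMessages(classify_cohort(summarize_cohort(rec)))
  expect_gt(nrow(fl), 0)
  for (i in seq_len(nrow(fl))) {
    expect_true(fl$pattern_type[i] %in% applic[[fl$sign[i]]])
  }
})

test_that("a facility identical to the pooled reference gets no flags", {
  s <- mk_summary()
  r <- s
  r$hc_id <- "ALL"
  fl <- classify_facility(s, r)
  expect_equal(nrow(fl), 0L)
})

test_that("one sign can carry both a skipper and a repeater flag", {
  s <- mk_summary(missing_frac = 0.45, modal_frac = 0.55,
                  top3_cum_frac = 0.70)
  r <- ref_row(missing_frac = 0.10, modal_frac = 0.05,
               top3_cum_frac = 0.13)
  fl <- classify_facility(s, r)
  expect_setequal(fl$pattern_type, c("skipper", "mono_repeater"))
  expect_equal(unique(fl$sign), "resp_rate")
})

test_that("insufficient-data pairs are skipped with a notice", {
  s <- mk_summary(missing_frac = 0.45, n_measured = 5L,
                  sufficient_n = FALSE)
  r <- ref_row(missing_frac = 0.05)
  expect_message(fl <- classify_facility(s, r),
                 class = "signgaps_insufficient_data")
  expect_equal(nrow(fl), 0L)
})

test_that("facility selection matches a brute-force two-clause oracle", {
  sel_oracle <- function(flags) {
    out <- character(0)
    for (hc in unique(flags$hc_id)) {
      f <- flags[flags$hc_id == hc, ]
      if (length(unique(f$sign)) >= 2 &&
          any(f$severity %in% c("moderate", "severe"))) {
        out <- c(out, hc)
      }
    }
    sort(out)
  }
  one_moderate <- tibble::tibble(
    hc_id = "HC-01", sign = c("muac", "height"),
    pattern_type = c("skipper", "skipper"),
    severity = c("moderate", "mild"), evidence = "{}")
  expect_equal(select_health_centers(one_moderate), "HC-01")
  single_mild <- tibble::tibble(hc_id = "HC-02", sign = "muac",
                                pattern_type = "skipper",
                                severity = "mild", evidence = "{}")
  expect_equal(select_health_centers(single_mild), character(0))

  set.seed(99)
  for (i in 1:200) {
    n <- sample(0:12, 1)
    flags <- tibble::tibble(
      hc_id = sample(sprintf("HC-%02d", 1:4), n, replace = TRUE),
      sign = sample(c(SIGN_IDS, Z_INDICATORS), n, replace = TRUE),
      pattern_type = sample(c("skipper", "mono_repeater",
                              "multi_repeater", "wrongly_evaluated"),
                            n, replace = TRUE),
      severity = sample(c("mild", "moderate", "severe"), n, replace = TRUE),
      evidence = "{}")
    expect_identical(select_health_centers(flags), sel_oracle(flags))
  }
})

test_that("threshold YAML overrides merge with defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("skipper_bands: {mild: 0.02, moderate: 0.08, severe: 0.2}",
               "plausible_ranges:",
               "  temperature: [35, 40.5]"), path)
  cfg <- read_threshold_config(path)
  expect_equal(unname(cfg$skipper_bands["mild"]), 0.02)
  expect_equal(cfg$plausible_ranges$temperature, c(35, 40.5))
  expect_equal(unname(cfg$repeater_freq_bands["severe"]), 0.30)
  expect_error(threshold_config(skipper_bands = c(mild = 0.3,
                                                  moderate = 0.2,
                                                  severe = 0.1)),
               "increasing")
})
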