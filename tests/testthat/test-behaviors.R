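base_cohort <- function(n_fac = 2, n = 8000, seed = 21) {
  generate_cohort(cohort_config(n_facilities = n_fac, n_per_facility = n),
                  seed = seed)
}

test_that("skipper raises the missing fraction by its intensity", {
  rec <- base_cohort()
  beh <- behavior_spec("skipper", 0.35)
  out <- inject_behavior(rec, "HC-01", "height", beh, seed = 1)
  el <- out$hc_id == "HC-01" & out$height_status != "not_applicable"
  p0 <- mean(rec$height_status[rec$hc_id == "HC-01" &
                                 rec$height_status != "not_applicable"] ==
               "not_feasible")
  p1 <- mean(out$height_status[el] == "not_feasible")
  expect_equal(p1, p0 + 0.35, tolerance = 0.02)
})

test_that("mono spike dominates the distribution at high intensity", {
  rec <- base_cohort(n_fac = 1, n = 10000)
  beh <- behavior_spec("mono_repeater", 0.5, target_values = 36.5)
  out <- inject_behavior(rec, "HC-01", "temperature", beh, seed = 2)
  v <- out$temperature_value[out$temperature_status == "measured"]
  tab <- sort(table(v), decreasing = TRUE)
  expect_equal(as.numeric(names(tab)[1]), 36.5)
  expect_gte(tab[[1]] / length(v), 0.5)
})

test_that("zero intensity is the identity and locality holds", {
  rec <- base_cohort(n_fac = 3, n = 500)
  beh0 <- behavior_spec("mono_repeater", 0, target_values = 36.5)
  expect_identical(inject_behavior(rec, "HC-01", "temperature", beh0,
                                   seed = 4), rec)
  beh <- behavior_spec("wrongly_evaluated", 0.5)
  out <- inject_behavior(rec, "HC-02", "weight", beh, seed = 4)
  expect_identical(out[out$hc_id != "HC-02", ], rec[rec$hc_id != "HC-02", ])
  # untouched signs of the targeted facility are intact too
  expect_identical(out$temperature_value, rec$temperature_value)
})

test_that("each behaviour's target statistic is monotone in intensity", {
  rec <- base_cohort(n_fac = 1, n = 6000, seed = 31)
  intensities <- c(0.05, 0.15, 0.3, 0.5)
  stat <- function(out, what) {
    el <- out$resp_rate_status != "not_applicable"
    v <- out$resp_rate_value[out$resp_rate_status == "measured"]
    switch(what,
           missing = mean(out$resp_rate_status[el] == "not_feasible"),
           modal = max(table(v)) / length(v),
           top3 = sum(sort(table(v), decreasing = TRUE)[1:3]) / length(v))
  }
  wz <- function(out) {
    z <- add_zscores(out)$weight_for_age_z_raw
    mean(abs(z) > 2, na.rm = TRUE)
  }
  series <- list(
    missing = vapply(intensities, function(i) {
      stat(inject_behavior(rec, "HC-01", "resp_rate",
                           behavior_spec("skipper", i), seed = 7),
           "missing")
    }, numeric(1)),
    modal = vapply(intensities, function(i) {
      stat(inject_behavior(rec, "HC-01", "resp_rate",
                           behavior_spec("mono_repeater", i, 35),
                           seed = 7), "modal")
    }, numeric(1)),
    top3 = vapply(intensities, function(i) {
      stat(inject_behavior(rec, "HC-01", "resp_rate",
                           behavior_spec("multi_repeater", i,
                                         c(34, 35, 36)), seed = 7),
           "top3")
    }, numeric(1)),
    extreme_z = vapply(intensities, function(i) {
      wz(inject_behavior(rec, "HC-01", "weight",
                         behavior_spec("wrongly_evaluated", i), seed = 7))
    }, numeric(1)))
  for (nm in names(series)) {
    expect_true(all(diff(series[[nm]]) >= 0), label = nm)
  }
})

test_that("invalid behaviour specs and over-intense injections error/warn", {
  expect_error(behavior_spec("mono_repeater", 0.2, c(36, 37)),
               "exactly 1 target")
  expect_error(behavior_spec("multi_repeater", 0.2, 36.5), "2-3 target")
  expect_error(behavior_spec("multi_repeater", 0.2, c(34, 35, 36, 37)),
               "2-3 target")
  expect_error(behavior_spec("skipper", -0.1))
  rec <- base_cohort(n_fac = 1, n = 200)
  expect_warning(
    inject_behavior(rec, "HC-01", "height", behavior_spec("skipper", 0.99),
                    seed = 3),
    "clipped")
  expect_error(
    inject_behavior(rec, "HC-01", "pulse",
                    behavior_spec("skipper", 0.1), seed = 3),
    "unknown sign_id")
})
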