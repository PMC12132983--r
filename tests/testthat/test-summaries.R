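test_that("degenerate and simple summaries are exact", {
  rec <- make_records(rep(36.5, 10))
  s <- summarize_sign(rec, "HC-01", "temperature")
  expect_equal(s$modal_frac, 1.0)
  expect_equal(s$iqr, 0)
  expect_equal(s$median, 36.5)
  expect_false(s$sufficient_n)  # 10 < 20 measured

  rec2 <- make_records(rep(37, 80),
                       status = c(rep("measured", 80),
                                  rep("not_feasible", 20)))
  s2 <- summarize_sign(rec2, "HC-01", "temperature")
  expect_equal(s2$missing_frac, 0.20)
  expect_equal(s2$n_eligible, 100L)
  expect_true(s2$sufficient_n)
})

test_that("median and IQR match a brute-force quantile oracle", {
  rec <- make_records(as.numeric(1:100))
  s <- summarize_sign(rec, "HC-01", "temperature")
  expect_equal(s$median, oracle_quantile(1:100, 0.5))
  expect_equal(s$iqr, oracle_quantile(1:100, 0.75) -
                 oracle_quantile(1:100, 0.25))
  set.seed(77)
  for (i in 1:25) {
    v <- round(runif(sample(5:60, 1), 30, 45), 1)
    s <- summarize_sign(make_records(v), "HC-01", "temperature")
    expect_equal(s$median, oracle_quantile(v, 0.5))
    expect_equal(s$iqr,
                 oracle_quantile(v, 0.75) - oracle_quantile(v, 0.25))
  }
})

test_that("modal ties break to the smallest value", {
  rec <- make_records(c(36.0, 36.0, 37.0, 37.0, 38.0))
  s <- summarize_sign(rec, "HC-01", "temperature")
  expect_equal(s$modal_value, 36.0)
  expect_equal(s$modal_frac, 0.4)
  expect_equal(s$top3_cum_frac, 1.0)
})

test_that("estimated weight counts as missing; empty cells are marked", {
  rec <- make_records(rep(12, 60),
                      status = c(rep("measured", 60),
                                 rep("estimated", 30),
                                 rep("not_feasible", 10)),
                      sign = "weight")
  s <- summarize_sign(rec, "HC-01", "weight")
  expect_equal(s$missing_frac, 0.4)
  expect_equal(s$n_measured, 60L)

  none <- make_records(numeric(0), status = character(0))
  s0 <- summarize_sign(none, "HC-01", "temperature")
  expect_equal(s0$n_eligible, 0L)
  expect_false(s0$sufficient_n)
  expect_true(is.na(s0$modal_frac))
})

test_that("z-score summaries count extremes among computable records", {
  rec <- make_records(rep(10, 4), sign = "weight")
  rec$weight_for_age_z_raw <- c(-2.5, 0, 0, 2.5)
  rec$weight_for_age_z <- c(-3L, 0L, 0L, 3L)
  s <- summarize_zscores(rec, "HC-01", "weight_for_age")
  expect_equal(s$extreme_z_frac, 0.5)
  rec$weight_for_age_z_raw <- rep(0, 4)
  rec$weight_for_age_z <- rep(0L, 4)
  expect_equal(summarize_zscores(rec, "HC-01",
                                 "weight_for_age")$extreme_z_frac, 0)
})

test_that("pooled reference equals per-facility identities", {
  rec1 <- make_records(rep(36, 30), hc_id = "HC-01")
  s_one <- summarize_sign(rec1, "HC-01", "temperature")
  pooled <- pooled_reference(rec1, "temperature")
  expect_equal(pooled[-1], s_one[-1])  # all but hc_id

  rec2 <- dplyr::bind_rows(make_records(rep(36, 30), hc_id = "HC-01"),
                           make_records(rep(38, 30), hc_id = "HC-02"))
  expect_equal(pooled_reference(rec2, "temperature")$mean, 37)
})

test_that("aggregation is consistent and permutation invariant", {
  cfg <- cohort_config(n_facilities = 5, n_per_facility = 400)
  rec <- generate_cohort(cfg, seed = 23)
  s <- summarize_cohort(rec, signs = c("temperature", "muac"))
  for (sg in c("temperature", "muac")) {
    per_fac <- s[s$hc_id != "ALL" & s$sign == sg, ]
    all_row <- s[s$hc_id == "ALL" & s$sign == sg, ]
    expect_equal(sum(per_fac$n_eligible), all_row$n_eligible)
    expect_equal(sum(per_fac$n_measured), all_row$n_measured)
  }
  shuffled <- rec[sample.int(nrow(rec)), ]
  s2 <- summarize_cohort(shuffled, signs = c("temperature", "muac"))
  expect_equal(as.data.frame(s2), as.data.frame(s))
})

test_that("summaries CSV round-trips including top-3 serialization", {
  rec <- generate_cohort(cohort_config(n_facilities = 2,
                                       n_per_facility = 300), seed = 3)
  s <- summarize_cohort(rec, signs = "temperature")
  path <- tempfile(fileext = ".csv")
  write_summaries(s, path)
  back <- read_summaries(path)
  expect_equal(back$top3, s$top3)
  expect_equal(back$modal_frac, s$modal_frac)
  expect_match(s$top3[1], "^[-0-9.]+:[0-9.]+(;[-0-9.]+:[0-9.]+){0,2}$")
})
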