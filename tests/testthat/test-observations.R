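obs <- build_observation_records()

test_that("the fixture reproduces the per-sign performance tallies", {
  tal <- tabulate_observations(obs)
  row <- function(s) tal[tal$sign == s, ]
  expect_equal(row("temperature")$n_total, 188L)
  expect_equal(row("temperature")$pct_insufficient, 67)
  expect_equal(row("weight")$pct_insufficient, 70)
  expect_equal(row("height")$pct_insufficient, 54)
  expect_equal(row("height")$pct_skipped, 21)
  expect_equal(row("height")$n_skipped, 39L)
  expect_equal(row("height")$n_insufficient, 101L)
  # counts always conserve: skipped + sufficient + insufficient = total
  expect_equal(tal$n_skipped + tal$n_sufficient + tal$n_insufficient,
               tal$n_total)
})

test_that("reason tallies reproduce every packaged count and prevalence", {
  fixture <- readr::read_csv(
    system.file("extdata", "observation_reasons.csv",
                package = "signgaps"), show_col_types = FALSE)
  got <- tabulate_all_reasons(obs)
  expect_equal(nrow(got), nrow(fixture))
  key <- function(d) paste(d$sign, d$category, d$code)
  got <- got[match(key(fixture), key(got)), ]
  expect_equal(got$count, fixture$count)
  # spot checks against the printed prevalences
  pick <- function(s, cat, code) got[got$sign == s & got$category == cat &
                                       got$code == code, ]
  expect_equal(pick("muac", "insufficient", "ribbon_location")$prevalence,
               91)
  expect_equal(pick("temperature", "insufficient",
                    "thermo_distance")$prevalence, 81)
  expect_equal(pick("resp_rate", "skip", "not_necessary")$prevalence, 60)
  expect_equal(pick("heart_rate", "skip", "not_necessary")$prevalence, 67)
  expect_true(all(got$prevalence >= 0 & got$prevalence <= 100))
  expect_true(all(got$count <= got$n_category))
})

test_that("multi-select reasons can sum past 100% within a category", {
  hr <- tabulate_reasons(obs, "heart_rate", "skip")
  expect_gt(sum(hr$prevalence), 100)
  two <- hr[hr$code %in% c("not_necessary", "too_time_consuming"), ]
  expect_setequal(two$prevalence, c(67, 52))
})

test_that("single-record categories give 100% prevalence", {
  rec <- tibble::tibble(
    consultation_id = "X1", hc_id = "H", sign = "temperature",
    performed = FALSE, quality = NA_character_, method = NA_character_,
    reasons = "forgot")
  t1 <- tabulate_reasons(rec, "temperature", "skip")
  expect_equal(t1$prevalence, 100)
  expect_equal(t1$count, 1L)
})

test_that("method comparison reproduces the app-vs-timer split", {
  cmp <- compare_methods(obs, "resp_rate")
  rrate <- cmp[cmp$method == "rrate", ]
  timer <- cmp[cmp$method == "timer", ]
  expect_equal(rrate$n, 39L)
  expect_equal(rrate$n_sufficient, 29L)
  expect_equal(rrate$pct_sufficient, 74)
  expect_equal(timer$n_sufficient, 18L)
  expect_equal(timer$pct_sufficient, 46)
  # a sign with no method attribute yields an empty comparison
  expect_equal(nrow(compare_methods(obs, "temperature")), 0L)
})

test_that("validation rejects malformed observation records", {
  bad <- obs
  bad$quality[which(!bad$performed)[1]] <- "sufficient"
  expect_error(validate_observations(bad), "quality recorded for skipped")
  bad2 <- obs
  bad2$reasons[1] <- "made_up_code"
  expect_error(validate_observations(bad2), "made_up_code")
  bad3 <- obs
  bad3$quality[which(bad3$performed)[1]] <- NA_character_
  expect_error(validate_observations(bad3), "sufficient|insufficient")
})

test_that("observation records survive a CSV round-trip", {
  path <- tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$performed, obs$performed)
  expect_equal(back$reasons, obs$reasons)
  expect_equal(tabulate_observations(back), tabulate_observations(obs))
})

test_that("the record expansion is reproducible for a given seed", {
  expect_identical(build_observation_records(seed = 5),
                   build_observation_records(seed = 5))
  expect_false(identical(build_observation_records(seed = 5)$reasons,
                         build_observation_records(seed = 6)$reasons))
})
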