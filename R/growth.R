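#' Smooth synthetic growth median curves
#'
#' Parametric median curves used both to build the bundled synthetic
#' growth-reference table and to generate baseline anthropometry in the
#' cohort simulator. They are deliberately simple piecewise-linear (in age)
#' approximations of child growth — adequate because every analysis in the
#' package is relative to the bundled table, never to external standards.
#'
#' `weight_for_height` is defined by composition: the median weight at the
#' age whose median height equals the given height, so that the three
#' curves are mutually consistent and baseline z-scores centre on zero.
#'
#' @param indicator One of `"weight_for_age"`, `"muac_for_age"`,
#'   `"height_for_age"`, `"weight_for_height"`.
#' @param key Age in days (age-keyed indicators) or height in cm
#'   (`weight_for_height`).
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Median measurement in the indicator's unit (kg or cm).
#' @export
growth_median <- function(indicator, key, sex) {
  sex_factor <- ifelse(sex == "male", 1.015, 0.985)
  med <- switch(
    indicator,
    weight_for_age = {
      a <- key / 365.25
      ifelse(a < 1, 3.3 + 6.7 * a, 10 + 2.15 * (a - 1))
    },
    height_for_age = {
      a <- key / 365.25
      ifelse(a < 1, 50 + 25 * a, 75 + 6.2 * (a - 1))
    },
    muac_for_age = {
      a <- key / 365.25
      12.5 + 0.55 * a
    },
    weight_for_height = {
      # invert the height curve, then read the weight curve at that age
      a <- ifelse(key < 75, (key - 50) / 25, (key - 75) / 6.2 + 1)
      a <- pmax(a, 0)
      ifelse(a < 1, 3.3 + 6.7 * a, 10 + 2.15 * (a - 1))
    },
    stop("unknown indicator: ", indicator, call. = FALSE)
  )
  med * sex_factor
}

# LMS shape parameters per indicator (synthetic reference)
LMS_SHAPE <- list(
  muac_for_age      = list(L = 0.4, S = 0.07),
  weight_for_age    = list(L = 0.25, S = 0.12),
  weight_for_height = list(L = 0.2, S = 0.15)
)

#' Build the synthetic LMS growth-reference table
#'
#' Tabulates the [growth_median()] curves on a regular grid — monthly ages
#' from 61 days to 5 years for the age-keyed indicators, 0.5 cm height
#' steps from 45 to 120 cm for weight-for-height — with constant L and S
#' per indicator. This is the generator of the bundled
#' `growth_reference_synthetic.csv`.
#'
#' @return Tibble with columns `indicator`, `sex`, `key`, `L`, `M`, `S`.
#' @export
make_synthetic_growth_reference <- function() {
  age_grid <- unique(round(c(61, seq(91, 1826, by = 30.4375), 1826)))
  height_grid <- seq(45, 120, by = 0.5)
  rows <- purrr::map_dfr(names(LMS_SHAPE), function(ind) {
    keys <- if (ind == "weight_for_height") height_grid else age_grid
    purrr::map_dfr(c("male", "female"), function(sx) {
      tibble::tibble(
        indicator = ind, sex = sx, key = keys,
        L = LMS_SHAPE[[ind]]$L,
        M = round(growth_median(ind, keys, sx), 4),
        S = LMS_SHAPE[[ind]]$S)
    })
  })
  rows
}

#' Load and validate a growth-reference table
#'
#' @param path CSV with columns `indicator`, `sex`, `key`, `L`, `M`, `S`.
#'   Defaults to the bundled synthetic reference.
#' @return A `growth_reference` object (validated tibble).
#' @details Validation enforces `M > 0`, `S > 0` and strictly increasing
#'   keys within each (indicator, sex) series; violations are load errors.
#'   Lookups between grid points use linear interpolation of L, M and S.
#' @export
load_growth_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "growth_reference_synthetic.csv",
                        package = "signgaps", mustWork = TRUE)
  }
  ref <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           indicator = readr::col_character(),
                           sex = readr::col_character(),
                           key = readr::col_double(),
                           L = readr::col_double(),
                           M = readr::col_double(),
                           S = readr::col_double()))
  required <- c("indicator", "sex", "key", "L", "M", "S")
  if (!all(required %in% names(ref))) {
    stop("growth reference must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("growth reference contains non-positive M or S", call. = FALSE)
  }
  bad <- ref |>
    dplyr::group_by(.data$indicator, .data$sex) |>
    dplyr::summarise(mono = all(diff(.data$key) > 0), .groups = "drop")
  if (!all(bad$mono)) {
    stop("growth reference keys must be strictly increasing within each ",
         "(indicator, sex) series", call. = FALSE)
  }
  class(ref) <- c("growth_reference", class(ref))
  ref
}

# interpolate (L, M, S) at `key` for one (indicator, sex) series
lms_at <- function(reference, indicator, sex, key) {
  rows <- reference[reference$indicator == indicator &
                      reference$sex == sex, ]
  if (nrow(rows) == 0L) {
    stop("no reference series for indicator '", indicator,
         "', sex '", sex, "'", call. = FALSE)
  }
  oob <- key < min(rows$key) | key > max(rows$key)
  if (any(oob, na.rm = TRUE)) {
    stop("key outside reference coverage [", min(rows$key), ", ",
         max(rows$key), "] for ", indicator, call. = FALSE)
  }
  list(L = stats::approx(rows$key, rows$L, xout = key)$y,
       M = stats::approx(rows$key, rows$M, xout = key)$y,
       S = stats::approx(rows$key, rows$S, xout = key)$y)
}

# the LMS transform itself
lms_z <- function(x, L, M, S) {
  ifelse(abs(L) < 1e-12, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Compute a growth z-score from the reference table
#'
#' Applies the LMS transform `z = ((x/M)^L - 1) / (L * S)` (or
#' `log(x/M)/S` when `L = 0`) with parameters linearly interpolated at the
#' child's key, and clamps the rounded value to the integer range
#' `[-3, 3]` the consultation tool displays. Rounding is half away from
#' zero; the raw z is retained so either convention can be audited.
#'
#' @param indicator One of `Z_INDICATORS`.
#' @param measurement Positive measurement in the indicator's unit
#'   (MUAC cm or weight kg).
#' @param sex `"male"` or `"female"`.
#' @param key Age in days (age-keyed indicators) or height in cm
#'   (`weight_for_height`); must lie within reference coverage.
#' @param reference A [load_growth_reference()] table.
#' @return List with `indicator`, `raw_z` and integer `clamped_z`.
#' @export
compute_zscore <- function(indicator, measurement, sex, key, reference) {
  indicator <- match.arg(indicator, Z_INDICATORS)
  if (any(measurement <= 0, na.rm = TRUE)) {
    stop("measurement must be positive", call. = FALSE)
  }
  stopifnot(length(sex) == 1L || length(sex) == length(measurement),
            length(key) == 1L || length(key) == length(measurement))
  if (length(sex) == 1L) sex <- rep(sex, length(measurement))
  if (length(key) == 1L) key <- rep(key, length(measurement))
  raw <- rep(NA_real_, length(measurement))
  for (sx in unique(sex)) {
    idx <- which(sex == sx)
    p <- lms_at(reference, indicator, sx, key[idx])
    raw[idx] <- lms_z(measurement[idx], p$L, p$M, p$S)
  }
  list(indicator = indicator, raw_z = raw, clamped_z = clamp_z(raw))
}

# integer clamping of raw z to [-3, 3]
clamp_z <- function(raw_z) {
  as.integer(pmax(-3, pmin(3, round_half_away(raw_z))))
}

#' Append growth z-score columns to a consultation table
#'
#' For each of the three indicators, adds `<indicator>_z_raw` (the LMS
#' z-score) and `<indicator>_z` (the rounded value clamped to `[-3, 3]`).
#' Z-scores are computed only for children aged 2 months to 5 years with a
#' measured (not estimated, not missing) source sign and, for
#' weight-for-height, a measured height within the reference's height
#' coverage; everywhere else the columns are `NA`.
#'
#' @param records Consultation tibble from [generate_cohort()] or
#'   [read_consultations()].
#' @param reference A [load_growth_reference()] table.
#' @return `records` with six additional columns.
#' @export
add_zscores <- function(records, reference = load_growth_reference()) {
  age_ok <- records$age_days >= Z_AGE_MIN_DAYS &
    records$age_days <= Z_AGE_MAX_DAYS
  for (ind in Z_INDICATORS) {
    src <- Z_SOURCE_SIGN[[ind]]
    meas <- records[[paste0(src, "_value")]]
    measured <- records[[paste0(src, "_status")]] == "measured"
    if (ind == "weight_for_height") {
      key <- records$height_value
      key_ok <- records$height_status == "measured" & !is.na(key)
    } else {
      key <- as.double(records$age_days)
      key_ok <- TRUE
    }
    rows <- reference[reference$indicator == ind, ]
    in_cov <- !is.na(key) & key >= min(rows$key) & key <= max(rows$key)
    use <- which(age_ok & measured & key_ok & in_cov & !is.na(meas))
    raw <- rep(NA_real_, nrow(records))
    if (length(use) > 0L) {
      z <- compute_zscore(ind, meas[use], records$sex[use], key[use],
                          reference)
      raw[use] <- z$raw_z
    }
    records[[paste0(ind, "_z_raw")]] <- raw
    records[[paste0(ind, "_z")]] <- clamp_z(raw)
  }
  records
}
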