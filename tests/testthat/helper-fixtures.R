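# Shared fixtures and independent oracles for the test suite.

# minimal consultation frame carrying one sign, built by hand
make_records <- function(values, status = rep("measured", length(values)),
                         sign = "temperature", hc_id = "HC-01",
                         age_days = 1000L, respiratory_complaint = TRUE) {
  n <- length(status)
  rec <- tibble::tibble(
    consultation_id = sprintf("T%04d", seq_len(n)),
    hc_id = rep_len(hc_id, n),
    age_days = rep_len(age_days, n),
    sex = rep_len("female", n),
    respiratory_complaint = rep_len(respiratory_complaint, n))
  rec[[paste0(sign, "_status")]] <- status
  v <- rep(NA_real_, n)
  v[status == "measured"] <- values
  rec[[paste0(sign, "_value")]] <- v
  rec
}

# hand-built one-row summary, mirroring summarize_sign() output columns
mk_summary <- function(hc_id = "HC-01", sign = "resp_rate",
                       n_eligible = 1000L, n_measured = 900L,
                       missing_frac = 0.1, modal_value = 35,
                       modal_frac = 0.05, top3_cum_frac = 0.13,
                       mean = 35, median = 35, iqr = 13,
                       extreme_z_frac = NA_real_, sufficient_n = TRUE) {
  tibble::tibble(hc_id = hc_id, sign = sign, n_eligible = n_eligible,
                 n_measured = n_measured, missing_frac = missing_frac,
                 modal_value = modal_value, modal_frac = modal_frac,
                 top3 = NA_character_, top3_cum_frac = top3_cum_frac,
                 mean = mean, median = median, iqr = iqr,
                 extreme_z_frac = extreme_z_frac,
                 sufficient_n = sufficient_n)
}

# independent type-7 quantile: h = (n-1)p + 1, linear interpolation
# between order statistics
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# independent LMS z-score: manual bracketing + linear interpolation of
# L, M, S, then the transform, written without reusing package internals
oracle_lms_z <- function(ref, indicator, sex, key, x) {
  rows <- ref[ref$indicator == indicator & ref$sex == sex, ]
  rows <- rows[order(rows$key), ]
  i <- findInterval(key, rows$key)
  if (key == rows$key[i]) {
    L <- rows$L[i]; M <- rows$M[i]; S <- rows$S[i]
  } else {
    w <- (key - rows$key[i]) / (rows$key[i + 1] - rows$key[i])
    L <- rows$L[i] * (1 - w) + rows$L[i + 1] * w
    M <- rows$M[i] * (1 - w) + rows$M[i + 1] * w
    S <- rows$S[i] * (1 - w) + rows$S[i + 1] * w
  }
  if (abs(L) < 1e-12) log(x / M) / S else ((x / M)^L - 1) / (L * S)
}

# tiny growth reference with hand-picked LMS rows, via the loader
write_toy_reference <- function(L = 1, M1 = 10, M2 = 12, S = 0.1) {
  path <- tempfile(fileext = ".csv")
  df <- expand.grid(sex = c("male", "female"),
                    key = c(100, 200), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(c("muac_for_age", "weight_for_age",
                                 "weight_for_height"), function(ind) {
    d <- df
    d$indicator <- ind
    d$L <- L
    d$M <- ifelse(d$key == 100, M1, M2)
    d$S <- S
    d
  }))
  readr::write_csv(out[, c("indicator", "sex", "key", "L", "M", "S")], path)
  path
}
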