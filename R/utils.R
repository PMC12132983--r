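#' Round half away from zero
#'
#' Commercial rounding: 0.5 goes up, -0.5 goes down. Used for integer
#' percentages in tallies and for clamped integer z-scores, so printed
#' numbers are reproducible regardless of the platform's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# derive a stream of sub-seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

severity_levels <- c("mild", "moderate", "severe")

# max of two severities on the mild < moderate < severe ordering; NA = none
severity_max <- function(a, b) {
  ia <- match(a, severity_levels)
  ib <- match(b, severity_levels)
  out <- pmax(ia, ib, na.rm = TRUE)
  out[is.na(ia) & is.na(ib)] <- NA_integer_
  severity_levels[out]
}
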