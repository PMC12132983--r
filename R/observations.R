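#' Load the observation reason-code dictionary
#'
#' @param path YAML mapping reason codes to labels; defaults to the
#'   bundled dictionary.
#' @return Named character vector (code -> label).
#' @export
load_reason_codes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reason_codes.yaml",
                        package = "signgaps", mustWork = TRUE)
  }
  unlist(yaml::read_yaml(path))
}

# bundled count-level observation fixtures
observation_fixture_counts <- function() {
  p <- function(f) system.file("extdata", f, package = "signgaps",
                               mustWork = TRUE)
  list(
    counts = readr::read_csv(p("observation_counts_synthetic.csv"),
                             show_col_types = FALSE),
    methods = readr::read_csv(p("observation_methods_synthetic.csv"),
                              show_col_types = FALSE),
    reasons = readr::read_csv(p("observation_reasons.csv"),
                              show_col_types = FALSE))
}

#' Build the record-level observation fixture
#'
#' Expands the bundled count-level fixture (per-sign totals,
#' skipped/sufficient/insufficient splits, per-reason counts and the
#' respiratory-rate method split) into one row per consultation-sign
#' observation. Which particular record carries which status, method and
#' reason combination is arbitrary and seeded — only the marginal counts
#' are fixed, which is all the descriptive analysis consumes. Denominators
#' for MUAC, heart rate, SpO2 and respiratory rate are synthetic
#' reconstructions (the printed report gives only their skip/insufficient
#' percentages), so they are labelled as such in the fixture file names.
#'
#' @param seed Integer seed for the arbitrary-but-reproducible assignment.
#' @return Tibble with columns `consultation_id`, `hc_id`, `sign`,
#'   `performed`, `quality`, `method`, `reasons` (semicolon-separated
#'   codes, possibly empty).
#' @export
build_observation_records <- function(seed = 188L) {
  fx <- observation_fixture_counts()
  n_consult <- max(fx$counts$n_total)
  hcs <- sprintf("OHC-%02d", seq_len(10))
  consult <- tibble::tibble(
    consultation_id = sprintf("OBS%03d", seq_len(n_consult)),
    hc_id = rep(hcs, length.out = n_consult))
  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(fx$counts)), function(i) {
      ct <- fx$counts[i, ]
      idx <- if (ct$n_total == n_consult) seq_len(n_consult)
        else sort(sample.int(n_consult, ct$n_total))
      rec <- consult[idx, ]
      rec$sign <- ct$sign
      # seeded permutation of outcome slots
      slot <- sample(c(rep("skipped", ct$n_skipped),
                       rep("sufficient", ct$n_sufficient),
                       rep("insufficient", ct$n_insufficient)))
      rec$performed <- slot != "skipped"
      rec$quality <- ifelse(rec$performed, slot, NA_character_)
      rec$method <- NA_character_
      m <- fx$methods[fx$methods$sign == ct$sign, ]
      if (nrow(m) > 0L) {
        rec <- assign_methods(rec, m)
      }
      rec$reasons <- ""
      for (cat in c("skip", "insufficient")) {
        rs <- fx$reasons[fx$reasons$sign == ct$sign &
                           fx$reasons$category == cat, ]
        if (nrow(rs) == 0L) next
        pool <- if (cat == "skip") which(!rec$performed)
          else which(!is.na(rec$quality) & rec$quality == "insufficient")
        codes <- vector("list", length(pool))
        for (j in seq_len(nrow(rs))) {
          pick <- sample.int(length(pool), rs$count[j])
          for (k in pick) codes[[k]] <- c(codes[[k]], rs$code[j])
        }
        rec$reasons[pool] <-
          purrr::map_chr(codes, ~ paste(.x, collapse = ";"))
      }
      rec
    })
    dplyr::bind_rows(rows)
  })
}

# split performed records of one sign across measurement methods with the
# fixed (n, n_sufficient) margins
assign_methods <- function(rec, m) {
  suff <- which(rec$performed & rec$quality == "sufficient")
  insuff <- which(rec$performed & rec$quality == "insufficient")
  stopifnot(sum(m$n) == length(suff) + length(insuff),
            sum(m$n_sufficient) == length(suff))
  suff <- suff[sample.int(length(suff))]
  insuff <- insuff[sample.int(length(insuff))]
  s_at <- 0L
  i_at <- 0L
  for (j in seq_len(nrow(m))) {
    ns <- m$n_sufficient[j]
    ni <- m$n[j] - ns
    rec$method[suff[s_at + seq_len(ns)]] <- m$method[j]
    rec$method[insuff[i_at + seq_len(ni)]] <- m$method[j]
    s_at <- s_at + ns
    i_at <- i_at + ni
  }
  rec
}

#' Validate observation records
#'
#' Enforces the record invariants: `quality` present iff `performed`,
#' quality values in {sufficient, insufficient}, and every reason code
#' known to the dictionary. Skip reasons may only appear on skipped
#' records and quality reasons only on insufficient ones is not enforced
#' record-wise (codes are shared across categories); unknown codes are.
#'
#' @param records Observation tibble.
#' @param reason_codes Code dictionary from [load_reason_codes()].
#' @return `records` invisibly; errors describe offending rows.
#' @export
validate_observations <- function(records,
                                  reason_codes = load_reason_codes()) {
  bad_q <- which(!records$performed & !is.na(records$quality))
  if (length(bad_q) > 0L) {
    stop("quality recorded for skipped observations at rows: ",
         paste(utils::head(bad_q, 10), collapse = ", "), call. = FALSE)
  }
  bad_q2 <- which(records$performed &
                    !records$quality %in% c("sufficient", "insufficient"))
  if (length(bad_q2) > 0L) {
    stop("performed observations must have quality ",
         "'sufficient' or 'insufficient'; offending rows: ",
         paste(utils::head(bad_q2, 10), collapse = ", "), call. = FALSE)
  }
  codes <- unlist(strsplit(records$reasons[records$reasons != "" &
                                             !is.na(records$reasons)], ";"))
  unknown <- setdiff(unique(codes), names(reason_codes))
  if (length(unknown) > 0L) {
    rows <- which(vapply(strsplit(records$reasons, ";"),
                         function(x) any(x %in% unknown), logical(1)))
    stop("unknown reason code(s) ", paste(unknown, collapse = ", "),
         " at rows: ", paste(utils::head(rows, 10), collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Tally performance and quality of sign assessments
#'
#' One row per sign: counts of skipped, sufficient and insufficient
#' assessments and their integer percentages of the sign's total
#' (denominators differ across signs because eligibility differs).
#'
#' @param records Validated observation tibble.
#' @return Tibble of per-sign tallies.
#' @export
tabulate_observations <- function(records) {
  validate_observations(records)
  records |>
    dplyr::group_by(.data$sign) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_skipped = sum(!.data$performed),
      n_sufficient = sum(.data$performed &
                           .data$quality == "sufficient"),
      n_insufficient = sum(.data$performed &
                             .data$quality == "insufficient"),
      .groups = "drop") |>
    dplyr::mutate(
      pct_skipped = round_half_away(100 * .data$n_skipped / .data$n_total),
      pct_sufficient = round_half_away(100 * .data$n_sufficient /
                                         .data$n_total),
      pct_insufficient = round_half_away(100 * .data$n_insufficient /
                                           .data$n_total))
}

#' Tally multi-select reasons for one sign and category
#'
#' Counts each reason code over the records in the category (skipped
#' records for `"skip"`, insufficient-quality records for
#' `"insufficient"`). Prevalence is the count over the category size as an
#' integer percent; because reasons are multi-select the prevalences of a
#' category may sum past 100%.
#'
#' @param records Validated observation tibble.
#' @param sign_id Sign to tabulate.
#' @param category `"skip"` or `"insufficient"`.
#' @param reason_codes Code dictionary for labels.
#' @return Tibble with `sign`, `category`, `code`, `label`, `count`,
#'   `n_category`, `prevalence`, sorted by descending count.
#' @export
tabulate_reasons <- function(records, sign_id,
                             category = c("skip", "insufficient"),
                             reason_codes = load_reason_codes()) {
  category <- match.arg(category)
  validate_observations(records, reason_codes)
  sub <- records[records$sign == sign_id, ]
  sub <- if (category == "skip") sub[!sub$performed, ]
    else sub[sub$performed & sub$quality == "insufficient", ]
  n_cat <- nrow(sub)
  codes <- unlist(strsplit(sub$reasons[sub$reasons != ""], ";"))
  if (length(codes) == 0L) {
    return(tibble::tibble(sign = character(), category = character(),
                          code = character(), label = character(),
                          count = integer(), n_category = integer(),
                          prevalence = numeric()))
  }
  tab <- sort(table(codes), decreasing = TRUE)
  tibble::tibble(
    sign = sign_id, category = category,
    code = names(tab),
    label = unname(reason_codes[names(tab)]),
    count = as.integer(tab),
    n_category = n_cat,
    prevalence = round_half_away(100 * as.integer(tab) / n_cat))
}

#' Tally reasons for every sign and category present
#'
#' @inheritParams tabulate_reasons
#' @return Row-bound [tabulate_reasons()] output for every (sign,
#'   category) with at least one reason.
#' @export
tabulate_all_reasons <- function(records,
                                 reason_codes = load_reason_codes()) {
  combos <- expand.grid(sign = unique(records$sign),
                        category = c("skip", "insufficient"),
                        stringsAsFactors = FALSE)
  dplyr::bind_rows(purrr::map(seq_len(nrow(combos)), function(i) {
    tabulate_reasons(records, combos$sign[i], combos$category[i],
                     reason_codes)
  }))
}

#' Compare sufficiency across measurement methods
#'
#' For signs measured with more than one tool (respiratory rate: tap-based
#' mobile app vs a full-minute timer), reports per-method counts and the
#' percentage of sufficient-quality assessments. Methods with zero records
#' are omitted.
#'
#' @param records Validated observation tibble.
#' @param sign_id Sign whose methods to compare.
#' @param method_field Column carrying the method attribute.
#' @return Tibble with `method`, `n`, `n_sufficient`, `pct_sufficient`.
#' @export
compare_methods <- function(records, sign_id, method_field = "method") {
  sub <- records[records$sign == sign_id & records$performed &
                   !is.na(records[[method_field]]), ]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(method = character(), n = integer(),
                          n_sufficient = integer(),
                          pct_sufficient = numeric()))
  }
  sub |>
    dplyr::group_by(method = .data[[method_field]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_sufficient = sum(.data$quality == "sufficient"),
      .groups = "drop") |>
    dplyr::mutate(pct_sufficient = round_half_away(100 * .data$n_sufficient /
                                                     .data$n))
}

#' Write / read an observations CSV
#'
#' Columns: `consultation_id`, `hc_id`, `sign`, `performed` (yes/no),
#' `quality` (sufficient/insufficient/empty), `method` (optional),
#' `reasons` (semicolon-separated codes).
#'
#' @param records Observation tibble.
#' @param path CSV path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` the tibble with `performed` as logical.
#' @export
write_observations <- function(records, path) {
  out <- records
  out$performed <- ifelse(out$performed, "yes", "no")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  rec$performed <- rec$performed == "yes"
  rec$quality[rec$quality == ""] <- NA_character_
  rec$reasons[is.na(rec$reasons)] <- ""
  rec
}
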