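#' Build the facility-by-sign pattern matrix
#'
#' One row per facility, one column per sign and z-indicator, each cell
#' listing the detected patterns as `Type (severity)` joined by `" - "`
#' (e.g. `"Skipper (moderate) - Mono (mild)"`), plus a final `selected`
#' column reflecting the facility selection rule. Facilities without any
#' flag still get a row when listed in `facilities`.
#'
#' @param flags Flag tibble from [classify_cohort()].
#' @param selection Output of [select_health_centers()] (recomputed from
#'   `flags` when omitted).
#' @param facilities Facility ids to include as rows; defaults to the
#'   facilities present in `flags`.
#' @param columns Column order; defaults to the seven signs followed by
#'   the three z-indicators.
#' @return Tibble: `hc_id`, one character column per sign, `selected`
#'   ("Yes"/"No").
#' @export
build_pattern_matrix <- function(flags, selection = NULL,
                                 facilities = NULL, columns = NULL) {
  if (is.null(selection)) selection <- select_health_centers(flags)
  if (is.null(facilities)) facilities <- sort(unique(flags$hc_id))
  if (is.null(columns)) columns <- c(SIGN_IDS, Z_INDICATORS)
  labels <- c(skipper = "Skipper", mono_repeater = "Mono",
              multi_repeater = "Multi", wrongly_evaluated = "WE")
  out <- tibble::tibble(hc_id = facilities)
  for (col in columns) {
    out[[col]] <- vapply(facilities, USE.NAMES = FALSE, function(hc) {
      f <- flags[flags$hc_id == hc & flags$sign == col, ]
      if (nrow(f) == 0L) return("")
      f <- f[order(match(f$pattern_type, names(labels))), ]
      paste(sprintf("%s (%s)", labels[f$pattern_type], f$severity),
            collapse = " - ")
    }, character(1))
  }
  out$selected <- ifelse(facilities %in% selection, "Yes", "No")
  out
}

#' Render the diagnostic figure set
#'
#' Writes four figure families mirroring the supplementary visualisations
#' of a facility data-quality review: per-sign not-feasible/missing bar
#' charts, per-facility boxplots with the pooled distribution alongside,
#' per-facility density plots, and z-score histograms. Filenames are
#' deterministic (`missingness.png`, `boxplots_<sign>.png`,
#' `density_<sign>.png`, `zscores_<indicator>.png`).
#'
#' @param records Consultation tibble (with z columns for the z family).
#' @param summaries Output of [summarize_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param signs Signs for the boxplot/density families.
#' @return Invisible character vector of written paths; empty input is a
#'   no-op with a warning.
#' @export
render_figures <- function(records, summaries, out_dir,
                           signs = c("temperature", "muac", "heart_rate",
                                     "resp_rate", "spo2")) {
  if (is.null(records) || nrow(records) == 0L) {
    warning("no records; no figures rendered", call. = FALSE)
    return(invisible(character(0)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_fig <- function(p, file, width = 8, height = 5) {
    path <- file.path(out_dir, file)
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    paths <<- c(paths, path)
  }
  save_fig(plot_missingness(summaries), "missingness.png", height = 6)
  for (s in signs) {
    save_fig(plot_sign_boxplots(records, s), paste0("boxplots_", s, ".png"))
    save_fig(plot_sign_density(records, s), paste0("density_", s, ".png"))
  }
  for (ind in intersect(paste0(Z_INDICATORS, "_z_raw"), names(records))) {
    ind <- sub("_z_raw$", "", ind)
    save_fig(plot_zscore_hist(records, ind),
             paste0("zscores_", ind, ".png"))
  }
  invisible(paths)
}

#' @rdname render_figures
#' @export
plot_missingness <- function(summaries) {
  d <- summaries[summaries$hc_id != "ALL" & !is.na(summaries$missing_frac), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hc_id, y = .data$missing_frac)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~sign, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Missing / not feasible fraction") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

long_values <- function(records, sign_id) {
  v <- records[[paste0(sign_id, "_value")]]
  keep <- records[[paste0(sign_id, "_status")]] == "measured" & !is.na(v)
  tibble::tibble(hc_id = records$hc_id[keep], value = v[keep])
}

#' @rdname render_figures
#' @param sign_id Sign to plot.
#' @export
plot_sign_boxplots <- function(records, sign_id) {
  d <- long_values(records, sign_id)
  d <- dplyr::bind_rows(d, dplyr::mutate(d, hc_id = "ALL"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hc_id, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(title = sign_id, x = NULL, y = sign_id) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname render_figures
#' @export
plot_sign_density <- function(records, sign_id) {
  d <- long_values(records, sign_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~hc_id, scales = "free_y") +
    ggplot2::labs(title = sign_id, x = sign_id, y = "density") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname render_figures
#' @param indicator Z-indicator to plot.
#' @export
plot_zscore_hist <- function(records, indicator) {
  z <- records[[paste0(indicator, "_z_raw")]]
  d <- tibble::tibble(hc_id = records$hc_id, z = z)
  d <- d[!is.na(d$z), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(binwidth = 0.25, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~hc_id, scales = "free_y") +
    ggplot2::labs(title = indicator, x = "z-score", y = "count") +
    ggplot2::theme_minimal(base_size = 9)
}
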