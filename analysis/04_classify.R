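#!/usr/bin/env Rscript
# Step 4: pattern classification and facility selection.
#
# Labels each facility-sign pair with skipper / mono-repeater /
# multi-repeater / wrongly-evaluated patterns and mild/moderate/severe
# levels against the pooled reference, applies the two-clause selection
# rule (>= 2 flagged signs, at least one moderate-or-severe), and writes
# the facility-by-sign pattern matrix plus diagnostic figures.

library(signgaps)

records <- read_consultations("results/consultations_z.csv")
summaries <- read_summaries("results/summaries.csv")
config <- read_threshold_config(system.file("extdata", "thresholds.yaml",
                                            package = "signgaps"))

flags <- classify_cohort(summaries, config)
write_flags(flags, "results/flags.csv")

selected <- select_health_centers(flags)
writeLines(selected, "results/selected_health_centers.txt")

matrix <- build_pattern_matrix(flags, selected,
                               facilities = sort(unique(records$hc_id)))
readr::write_csv(matrix, "results/pattern_matrix.csv")

figs <- render_figures(records, summaries, "results/figures")

cat("flags:", nrow(flags), "\n")
print(as.data.frame(flags[, c("hc_id", "sign", "pattern_type",
                              "severity")]), row.names = FALSE)
cat("selected for observation:", paste(selected, collapse = ", "), "\n")
cat("figures:", length(figs), "files under results/figures/\n")
cat("wrote results/flags.csv, results/pattern_matrix.csv,",
    "results/selected_health_centers.txt\n")
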