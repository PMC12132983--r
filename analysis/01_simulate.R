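#!/usr/bin/env Rscript
# Step 1: simulate the multi-facility consultation cohort.
#
# Generates ~20,000 consultations across 16 health centres from the
# bundled demonstration config, which injects known measurement
# behaviours (skippers, repeaters, wrongly-evaluated) at a handful of
# facilities. Writes results/consultations.csv.

library(signgaps)

seed <- as.integer(Sys.getenv("SIGNGAPS_SEED", "20260101"))
dir.create("results", showWarnings = FALSE)

cfg <- read_cohort_config(system.file("extdata", "cohort_config.yaml",
                                      package = "signgaps"))
records <- generate_cohort(cfg, seed = seed)
write_consultations(records, "results/consultations.csv")

cat("seed:", seed, "\n")
cat("consultations:", nrow(records), "across",
    length(unique(records$hc_id)), "health centres\n")
cat("respiratory complaints:",
    sprintf("%.1f%%", 100 * mean(records$respiratory_complaint)), "\n")
cat("injected behaviours:", length(cfg$behaviors), "\n")
cat("wrote results/consultations.csv\n")
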