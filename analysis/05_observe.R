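#!/usr/bin/env Rscript
# Step 5: prospective-observation descriptive analysis.
#
# Expands the packaged count-level observation fixture to record level,
# then tabulates per-sign performed/skipped/quality proportions, the
# multi-select reasons for skipping or insufficient quality, and the
# app-vs-timer comparison for respiratory rate.

library(signgaps)

obs <- build_observation_records()
write_observations(obs, "results/observations.csv")

tallies <- tabulate_observations(obs)
readr::write_csv(tallies, "results/observation_tallies.csv")
cat("per-sign performance and quality:\n")
print(as.data.frame(tallies), row.names = FALSE)

reasons <- tabulate_all_reasons(obs)
readr::write_csv(reasons, "results/reason_tallies.csv")
cat("\nreason tallies:", nrow(reasons), "rows",
    "(multi-select; prevalences within a category may sum past 100%)\n")

cmp <- compare_methods(obs, "resp_rate")
readr::write_csv(cmp, "results/method_comparison.csv")
cat("\nrespiratory-rate method comparison:\n")
print(as.data.frame(cmp), row.names = FALSE)

cat("\nwrote results/observations.csv, observation_tallies.csv,",
    "reason_tallies.csv, method_comparison.csv\n")
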