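#!/usr/bin/env Rscript
# Step 3: per-facility summary statistics.
#
# Computes, for every facility-sign pair and for the pooled "ALL"
# reference: missing fraction, modal value and top-3 frequencies, mean,
# median, IQR, and extreme z-score fractions for the three growth
# indicators. Writes results/summaries.csv.

library(signgaps)

records <- read_consultations("results/consultations_z.csv")
summaries <- summarize_cohort(records)
write_summaries(summaries, "results/summaries.csv")

pooled <- summaries[summaries$hc_id == "ALL", ]
cat("summary rows:", nrow(summaries), "\n")
cat("pooled reference:\n")
print(as.data.frame(pooled[, c("sign", "n_eligible", "missing_frac",
                               "modal_value", "modal_frac", "median",
                               "iqr", "extreme_z_frac")]),
      digits = 3, row.names = FALSE)
cat("wrote results/summaries.csv\n")
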