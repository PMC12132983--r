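#!/usr/bin/env Rscript
# Step 2: growth z-scores.
#
# Attaches MUAC-for-age, weight-for-age and weight-for-height z-scores
# (raw and the clamped integer the consultation tool displays) for
# children aged 2 months to 5 years, using the bundled synthetic LMS
# reference. Writes results/consultations_z.csv.

library(signgaps)

records <- read_consultations("results/consultations.csv")
reference <- load_growth_reference()
records <- add_zscores(records, reference)
write_consultations(records, "results/consultations_z.csv")

for (ind in Z_INDICATORS) {
  raw <- records[[paste0(ind, "_z_raw")]]
  cat(sprintf("%-18s computable: %5d  extreme (|z|>2): %.1f%%\n",
              ind, sum(!is.na(raw)),
              100 * mean(abs(raw) > 2, na.rm = TRUE)))
}
cat("wrote results/consultations_z.csv\n")
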