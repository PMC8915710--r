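#!/usr/bin/env Rscript
# Step 2: read the cohort back from disk (exercising the text readers and
# their validation) and extract the subject-level waveform feature table:
# per-beat amplitude/width/AUC aggregated over the last 5 s of rest and of
# strain, window RMS power, and the end-Valsalva / end-rest ratios,
# averaged over each subject's three trials.

suppressPackageStartupMessages(library(ppgvalsalva))

cohort <- read_cohort("scratch/cohort")
features <- cohort_features(cohort, window_len = 5)
write.csv(features, "results/features.csv", row.names = FALSE)

cat(sprintf("Extracted features for %d of %d subjects.\n",
            nrow(features), length(cohort)))
ov <- features$overload_15
cat(sprintf(
  "Mean amplitude ratio (end-Valsalva / end-rest): %.2f overloaded vs %.2f non-overloaded\n",
  mean(features$ratio_amplitude[ov]), mean(features$ratio_amplitude[!ov])))
cat("Feature table written to results/features.csv\n")
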