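#!/usr/bin/env Rscript
# Step 4: render the comparison report and the two figures: the
# predicted-vs-measured regression scatter and the Bland-Altman agreement
# plot (held-out predictions).

suppressPackageStartupMessages(library(ppgvalsalva))

fits <- readRDS("scratch/model_fits.rds")
reg <- fits$reg
report <- read.csv("results/report_table.csv")

cat("== Model comparison (pooled fivefold CV) ==\n")
for (case in unique(report$case)) {
  cat(sprintf("\n%s  [terms: %s]\n", case,
              report$terms[report$case == case & report$arm == "model"][1]))
  sub <- report[report$case == case, ]
  for (arm in unique(sub$arm)) {
    vals <- sub[sub$arm == arm, ]
    cat(sprintf("  %-6s %s\n", arm,
                paste(sprintf("%s=%.3f", vals$metric, vals$value),
                      collapse = "  ")))
  }
}

features <- read.csv("results/features.csv")
pdf("results/figures.pdf", width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4.2, 4.2, 2.5, 1))
plot(reg$cv$predictions, features$filling_pressure,
     xlab = "Predicted filling pressure (mmHg, held-out)",
     ylab = "Measured filling pressure (mmHg)",
     main = sprintf("Waveform regression (CV R2 = %.2f)", reg$cv$cv_r2),
     pch = 19, col = ifelse(features$overload_15, "firebrick", "steelblue"))
abline(0, 1, lty = 2)
legend("topleft", c("> 15 mmHg", "<= 15 mmHg"), pch = 19,
       col = c("firebrick", "steelblue"), bty = "n")

ba <- reg$bland_altman_cv
plot(ba$data$mean, ba$data$diff,
     xlab = "Mean of predicted and measured (mmHg)",
     ylab = "Predicted - measured (mmHg)",
     main = "Bland-Altman (held-out)", pch = 19, col = "grey30")
abline(h = ba$bias, lwd = 2)
abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
dev.off()

cat("\nFigures written to results/figures.pdf\n")
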