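#!/usr/bin/env Rscript
# Stage 5 -- haptic vs non-haptic statistics.
#
# Paired-sample t-tests on per-subject accuracies (haptic minus non-haptic)
# and mean relative growth rates, per (feature, band, pattern) cell, plus
# the four report tables (mean accuracies per pattern, p-values, growth
# rates) under results/tables/.

suppressMessages(library(hapticEEG))

acc <- read.csv("results/classify/accuracy_by_subject.csv",
                stringsAsFactors = FALSE)
st <- accuracy_stats(acc, alpha = 0.05)
paths <- render_tables(acc, st, "results/tables", alpha = 0.05)
write.csv(st, "results/tables/stats_cells.csv", row.names = FALSE)

cat("wrote:", paste(basename(paths), collapse = ", "), "\n")
sig <- st[st$significant & !is.na(st$significant), ]
cat(sprintf("significant haptic improvements at alpha = 0.05: %d of %d cells\n",
            nrow(sig), nrow(st)))
print(sig[order(sig$p), c("feature", "band", "pattern", "p", "growth_pct")],
      digits = 3, row.names = FALSE)
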