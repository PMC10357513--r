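#!/usr/bin/env Rscript
# Stage 4 -- per-subject 4-class linear-SVM evaluation.
#
# Loads the stored feature tensors, assembles one dataset per
# (pattern, condition, feature kind, band row) cell -- band rows are the
# five bands plus the all-band "total" concatenation -- and evaluates each
# with 4-fold session-grouped, class-balanced cross-validation. Writes the
# per-subject accuracy table under results/classify/.

suppressMessages(library(hapticEEG))

feat_dir <- "results/features"
out <- "results/classify"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

files <- sort(list.files(feat_dir, pattern = "_features\\.rds$",
                         full.names = TRUE))
stopifnot(length(files) > 0)

band_rows <- c(eeg_bands()$name, "total")
kinds <- c("PSD", "DE", "DASM", "DCAU")
rows <- list()
for (f in files) {
  feats <- readRDS(f)
  meta <- do.call(rbind, lapply(feats, function(x) as.data.frame(x$meta)))
  for (pat in sort(unique(meta$pattern)))
    for (cond in c("non-haptic", "haptic"))
      for (kind in kinds)
        for (band in band_rows) {
          sel <- which(meta$pattern == pat & meta$condition == cond)
          acc <- tryCatch({
            ds <- assemble_dataset(lapply(feats[sel], `[[`, kind),
                                   meta$emotion[sel], meta$session[sel],
                                   band = band)
            crossval_svm(ds, k = 4, seed = 2024)
          }, error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = meta$subject[1], pattern = pat, condition = cond,
            feature = kind, band = band, accuracy = acc)
        }
  cat("  evaluated", meta$subject[1], "\n")
}
acc <- do.call(rbind, rows)
write.csv(acc, file.path(out, "accuracy_by_subject.csv"), row.names = FALSE)
m <- aggregate(accuracy ~ feature + band + condition, acc, mean)
cat("mean accuracy, gamma band:\n")
print(reshape(m[m$band == "gamma", ], idvar = "feature",
              timevar = "condition", direction = "wide", drop = "band"),
      digits = 3, row.names = FALSE)
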