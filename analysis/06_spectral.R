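#!/usr/bin/env Rscript
# Stage 6 -- time-frequency and topographic summaries.
#
# Morlet-wavelet time-frequency maps (5-s non-overlapping windows,
# channel-mean energy) per condition, and baseline-subtracted DE scalp
# topographies per emotion and band, written as CSV value tables under
# results/spectral/. These are the numeric counterparts of the usual
# time-frequency figures and topographic maps.

suppressMessages(library(hapticEEG))

pre_dir <- "results/preprocessed"
feat_dir <- "results/features"
out <- "results/spectral"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## wavelet maps: first subject, first joy session, both conditions
vhdr <- sort(list.files(pre_dir, pattern = "\\.vhdr$", full.names = TRUE))[1]
rec <- read_recording(vhdr)
segs <- segment_sessions(rec)
is_joy <- vapply(segs, function(s) s$emotion == "joy", TRUE)
for (cond in c("non-haptic", "haptic")) {
  seg <- segs[is_joy &
                vapply(segs, function(s) s$condition == cond, TRUE)][[1]]
  tf <- tf_wavelet(seg, window_s = 5)
  tab <- data.frame(freq_hz = tf$freqs, tf$energy)
  names(tab)[-1] <- paste0("win", seq_len(ncol(tf$energy)))
  write.csv(tab, file.path(out, paste0("tf_joy_", gsub("-", "", cond), ".csv")),
            row.names = FALSE)
}

## baseline-subtracted DE topographies averaged over subjects
files <- sort(list.files(feat_dir, pattern = "_features\\.rds$",
                         full.names = TRUE))
emotions <- c("joy", "sadness", "fear", "neutral")
for (emo in emotions) {
  de <- list(); de_base <- list()
  for (f in files) {
    feats <- readRDS(f)
    sel <- vapply(feats, function(x)
      x$meta$emotion == emo && x$meta$condition == "haptic", TRUE)
    de <- c(de, lapply(feats[sel], `[[`, "DE"))
    de_base <- c(de_base, lapply(feats[sel], `[[`, "DE_baseline"))
  }
  tv <- topo_de(de, de_base)
  tab <- cbind(tv$positions, as.data.frame(tv$values))
  write.csv(tab, file.path(out, paste0("topo_de_", emo, ".csv")),
            row.names = FALSE)
  gamma <- sort(tv$values[, "gamma"], decreasing = TRUE)
  cat(sprintf("  %s: strongest gamma activation at %s\n", emo,
              paste(names(gamma)[1:4], collapse = ", ")))
}
cat("wrote wavelet maps and", length(emotions), "topography tables\n")
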