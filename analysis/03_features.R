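#!/usr/bin/env Rscript
# Stage 3 -- extract window-level features.
#
# Segments each preprocessed recording into per-session condition halves
# (non-haptic first half / haptic second half, sharing the 5-s pre-clip
# baseline), and computes per 1-s window: five-band PSD (256-point STFT,
# Hanning taper), differential entropy (DE) of the band-filtered windows,
# and the DASM (28 hemispheric pairs) and DCAU (22 frontal-posterior pairs)
# DE differences. Tensors are stored under results/features/ with a CSV
# summary of per-band mean DE by emotion.

suppressMessages(library(hapticEEG))

pre_dir <- "results/preprocessed"
out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

usable <- montage_channels(standard_montage())
vhdrs <- sort(list.files(pre_dir, pattern = "\\.vhdr$", full.names = TRUE))
stopifnot(length(vhdrs) > 0)

summary_rows <- list()
for (f in vhdrs) {
  subject <- sub("\\.vhdr$", "", basename(f))
  rec <- read_recording(f, subject = subject)
  segs <- segment_sessions(rec)
  band_segs <- lapply(band_decompose_recording(rec), segment_sessions)
  feats <- lapply(seq_along(segs), function(i) {
    band_list <- lapply(names(band_segs), function(b) {
      s <- band_segs[[b]][[i]]; s$band <- b; s
    })
    de <- de_features(band_list)
    list(meta = segs[[i]][c("subject", "session", "emotion", "pattern",
                            "condition")],
         PSD = tensor_select_units(psd_features(segs[[i]]), usable),
         DE = tensor_select_units(de, usable),
         DASM = dasm_features(de), DCAU = dcau_features(de),
         DE_baseline = tensor_select_units(
           de_features(band_list, on = "baseline"), usable))
  })
  saveRDS(feats, file.path(out, paste0(subject, "_features.rds")))
  for (ft in feats)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      subject = subject, emotion = ft$meta$emotion,
      condition = ft$meta$condition,
      band = ft$DE$bands, mean_de = apply(ft$DE$values, 3, mean))
  cat(sprintf("  %s: %d segments x [%d windows x 63 ch x 5 bands]\n",
              subject, length(feats), dim(feats[[1]]$DE$values)[1]))
}
summ <- do.call(rbind, summary_rows)
agg <- aggregate(mean_de ~ band + emotion + condition, summ, mean)
write.csv(agg, file.path(out, "mean_de_by_emotion.csv"), row.names = FALSE)
cat("gamma-band DE by emotion (non-haptic vs haptic):\n")
print(reshape(agg[agg$band == "gamma", ], idvar = "emotion",
              timevar = "condition", direction = "wide", drop = "band"),
      digits = 3, row.names = FALSE)
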