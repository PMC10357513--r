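#!/usr/bin/env Rscript
# Stage 1 -- simulate the haptic-EEG experiment.
#
# Generates a desk-scale synthetic experiment (4 subjects, 16 sessions each,
# 32-s clips at 200 Hz; the full-protocol defaults of 16 subjects / 4-min
# clips at 1,000 Hz scale the same way) and writes the raw recordings as
# BrainVision triplets plus the experiment manifest and per-session haptic
# schedules under results/raw/.

suppressMessages(library(hapticEEG))

out <- "results/raw"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_subjects = 4, clip_s = 32, rest_s = 2, fs = 200,
                        seed = 2024)
saveRDS(cfg, file.path(out, "generator_config.rds"))

manifest <- list(); schedules <- list()
for (i in seq_len(cfg$n_subjects)) {
  rec <- generate_subject(cfg, i)
  write_recording(rec, file.path(out, rec$subject), "BrainVision")
  manifest[[i]] <- cbind(subject = rec$subject, rec$annotations)
  schedules[[i]] <- do.call(rbind, lapply(seq_len(nrow(rec$annotations)),
    function(j) {
      sch <- session_haptic_schedule(rec$annotations[j, ], seed = 2024 + i)
      if (!nrow(sch)) return(NULL)
      cbind(subject = rec$subject,
            session_id = rec$annotations$session_id[j], sch)
    }))
  cat(sprintf("  %s: %d channels, %.0f s, %d sessions\n", rec$subject,
              nrow(rec$samples), recording_duration(rec),
              nrow(rec$annotations)))
}
manifest <- do.call(rbind, manifest)
write_manifest(manifest, file.path(out, "manifest.csv"))
write.csv(do.call(rbind, schedules), file.path(out, "haptic_schedules.csv"),
          row.names = FALSE)

cat(sprintf("wrote %d subjects; per subject: %d sessions, %d haptic1 / %d haptic2\n",
            cfg$n_subjects, cfg$n_sessions,
            sum(manifest$pattern == "haptic1") / cfg$n_subjects,
            sum(manifest$pattern == "haptic2") / cfg$n_subjects))
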