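#!/usr/bin/env Rscript
# Stage 2 -- preprocess the raw recordings.
#
# Reads the BrainVision recordings written by stage 1 and applies the
# standard chain: decimation to 200 Hz, 50 Hz notch, 1-50 Hz zero-phase
# band-pass, common average re-referencing with FCz recovery. Writes the
# preprocessed recordings under results/preprocessed/. The ICA stage is
# available (`ica = TRUE`) but off here: these synthetic runs carry their
# EOG/line components only to exercise the filters, and stage timing stays
# interactive without it.

suppressMessages(library(hapticEEG))

raw_dir <- "results/raw"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vhdrs <- sort(list.files(raw_dir, pattern = "\\.vhdr$", full.names = TRUE))
stopifnot(length(vhdrs) > 0)

for (f in vhdrs) {
  subject <- sub("\\.vhdr$", "", basename(f))
  rec <- read_recording(f, subject = subject)
  pre <- preprocess_chain(rec, fs_target = 200, ica = FALSE)
  write_recording(pre, file.path(out, subject), "BrainVision")
  cat(sprintf("  %s: %d -> %d channels (FCz recovered), mean channel power %.1f uV^2\n",
              subject, nrow(rec$samples), nrow(pre$samples),
              mean(pre$samples^2)))
}
cat("preprocessed", length(vhdrs), "recordings\n")
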