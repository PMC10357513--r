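# Small builders shared across test files. Everything is generated in code;
# sizes are kept tiny so the default test run stays fast.

make_segment <- function(x, fs = 200, baseline = NULL, band = NULL,
                         emotion = "joy", condition = "non-haptic",
                         session = 1L, channel_names = NULL) {
  x <- as.matrix(x)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(x)))
  rownames(x) <- channel_names
  if (is.null(baseline)) baseline <- x[, seq_len(min(ncol(x), fs)), drop = FALSE]
  seg <- structure(
    list(samples = x, fs = fs, channel_names = channel_names,
         subject = "S01", session = session, emotion = emotion,
         pattern = "haptic1", condition = condition, baseline = baseline),
    class = "session_segment")
  if (!is.null(band)) seg$band <- band
  seg
}

# band-limited unit-variance noise through the package's own generator helper
bl_noise <- function(n, fs, lo, hi) hapticEEG:::bandlimited_noise(n, fs, lo, hi)

sinusoid_recording <- function(freqs, amps, fs = 1000, dur = 10, n_ch = 2,
                               phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t + phase),
                      freqs, amps))
  eeg_recording(matrix(rep(x, each = n_ch), nrow = n_ch, byrow = FALSE),
                fs, paste0("ch", seq_len(n_ch)))
}

band_power_ratio <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
  f <- sp$freq * fs
  sum(sp$spec[f >= lo & f <= hi]) / sum(sp$spec)
}

# small scaled-down generator config used across tests
tiny_config <- function(..., seed = 42) {
  generator_config(n_subjects = 1, clip_s = 16, rest_s = 2, fs = 200,
                   eog_amp = 0, line_amp = 0, seed = seed, ...)
}
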