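test_that("decimation preserves passband and attenuates aliases", {
  rec <- sinusoid_recording(30, 1, fs = 1000, dur = 10)
  out <- resample_recording(rec, 200)
  expect_equal(ncol(out$samples), 2000)
  expect_equal(out$fs, 200)
  # 30 Hz amplitude preserved within 1% (ignore filter edges)
  core <- out$samples[1, 200:1800]
  t <- (199:1799) / 200
  amp <- 2 * abs(mean(core * exp(-2i * pi * 30 * t)))
  expect_equal(amp, 1, tolerance = 0.01)
  # 150 Hz attenuated by > 40 dB
  rec2 <- sinusoid_recording(150, 1, fs = 1000, dur = 10)
  out2 <- resample_recording(rec2, 200)
  p_in <- mean(rec2$samples[1, ]^2)
  p_out <- mean(out2$samples[1, 200:1800]^2)
  expect_lt(10 * log10(p_out / p_in), -40)
  expect_error(resample_recording(out, 400), "upsampling")
  expect_error(resample_recording(rec, 300), "integer")
})

test_that("band-pass removes DC and stop-band, passes mid-band", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- 5 + sin(2 * pi * 20 * t)
  rec <- eeg_recording(rbind(x, x), fs, c("a", "b"))
  out <- bandpass_recording(rec, 1, 50)
  expect_lt(abs(mean(out$samples[1, 400:1600])), 0.02)   # DC gone
  core <- out$samples[1, 400:1600]
  amp <- 2 * abs(mean(core * exp(-2i * pi * 20 * t[400:1600])))
  expect_equal(amp, 1, tolerance = 0.01)                 # 20 Hz intact
  expect_error(bandpass_recording(rec, 0, 50), "corner")
  expect_error(bandpass_recording(rec, 40, 20), "corner")
})

test_that("notch suppresses line frequency by > 30 dB", {
  fs <- 200
  rec <- sinusoid_recording(50, 1, fs = fs, dur = 10)
  out <- notch_recording(rec, 50)
  p_in <- mean(rec$samples[1, ]^2)
  p_out <- mean(out$samples[1, 400:1600]^2)
  expect_lt(10 * log10(p_out / p_in), -30)
  # neighbouring content survives
  rec2 <- sinusoid_recording(40, 1, fs = fs, dur = 10)
  out2 <- notch_recording(rec2, 50)
  expect_gt(mean(out2$samples[1, 400:1600]^2) / mean(rec2$samples[1, ]^2), 0.9)
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(5 * 100), 5), 100, paste0("c", 1:5))
  out <- rereference_car(rec, reconstruct_reference = FALSE)
  expect_lt(max(abs(colMeans(out$samples))), 1e-9)
  twice <- rereference_car(out, reconstruct_reference = FALSE)
  expect_equal(twice$samples, out$samples, tolerance = 1e-12)
  one <- eeg_recording(matrix(rnorm(100), 1), 100, "c1")
  expect_error(rereference_car(one), "at least 2")
})

test_that("CAR recovers the reference channel by the negation identity", {
  set.seed(5)
  n <- 200
  sources <- matrix(rnorm(4 * n), 4)           # true scalp potentials
  ref <- rnorm(n)                              # true FCz potential
  recorded <- sweep(sources, 2, ref)           # x_i = s_i - s_FCz
  rec <- eeg_recording(recorded, 100, paste0("c", 1:4))
  out <- rereference_car(rec)
  expect_true("FCz" %in% out$channel_names)
  # recovered FCz equals the CAR-referenced true reference potential
  expect_equal(unname(out$samples["FCz", ]),
               unname(ref - colMeans(sources)),
               tolerance = 1e-9)
})

test_that("segmentation yields two halves per session sharing the baseline", {
  cfg <- tiny_config()
  rec <- generate_subject(cfg, 1)
  segs <- segment_sessions(rec)
  expect_length(segs, 32)
  s <- segs[[1]]
  expect_equal(ncol(s$baseline), 5 * rec$fs)
  n_half <- floor(cfg$clip_s * rec$fs / 2)
  expect_equal(ncol(s$samples), n_half)
  expect_identical(segs[[1]]$condition, "non-haptic")
  expect_identical(segs[[2]]$condition, "haptic")
  expect_identical(segs[[1]]$baseline, segs[[2]]$baseline)
  # annotation outside the recording errors with the session named
  bad <- rec$annotations
  bad$clip_end_s[3] <- recording_duration(rec) + 10
  expect_error(segment_sessions(rec, bad), "session 3")
})

test_that("band decomposition isolates and partitions the spectrum", {
  fs <- 200
  set.seed(6)
  # broadband input shaped by the pipeline's own 1-50 Hz analysis filter,
  # so band-edge roll-offs match between the whole and its parts
  white <- eeg_recording(matrix(rnorm(4000), 1), fs, "c1")
  broad <- bandpass_recording(white, 1, 50)
  seg <- make_segment(broad$samples, fs = fs)
  out <- band_decompose(seg)
  expect_length(out, 5)
  expect_identical(names(out), eeg_bands()$name)
  v_bands <- vapply(out, function(s) var(s$samples[1, ]), 0)
  v_broad <- var(seg$samples[1, ])
  # zero-phase (two-pass) filtering squares |H|, so each interior band edge
  # passes 0.25 per neighbour; the five order-4 bands recover ~88% of the
  # broadband variance, never more than all of it
  expect_gt(sum(v_bands) / v_broad, 0.84)
  expect_lt(sum(v_bands) / v_broad, 1.02)
  # a pure 10 Hz tone lands in alpha
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  seg10 <- make_segment(rbind(sin(2 * pi * 10 * t)), fs = fs)
  out10 <- band_decompose(seg10)
  v10 <- vapply(out10, function(s) var(s$samples[1, ]), 0)
  expect_gt(v10[["alpha"]] / sum(v10), 0.95)
})

test_that("recording-level and per-segment band decomposition agree", {
  cfg <- tiny_config()
  rec <- preprocess_chain(generate_subject(cfg, 1))
  segs <- segment_sessions(rec)
  band_recs <- band_decompose_recording(rec)
  seg_gamma <- band_decompose(segs[[1]])$gamma
  rec_gamma <- segment_sessions(band_recs$gamma)[[1]]
  # same band content up to segment-edge filter transients
  core <- 200:(ncol(seg_gamma$samples) - 200)
  expect_equal(seg_gamma$samples[3, core], rec_gamma$samples[3, core],
               tolerance = 0.05)
})

test_that("preprocessing chain is seed-reproducible and keeps channel order", {
  cfg <- tiny_config(n_sessions = 4)
  rec <- generate_subject(cfg, 1)
  a <- preprocess_chain(rec, ica = FALSE)
  b <- preprocess_chain(rec, ica = FALSE)
  expect_identical(a$samples, b$samples)
  expect_identical(a$channel_names[seq_along(rec$channel_names)],
                   rec$channel_names)
})
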