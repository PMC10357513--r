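test_that("wavelet map localizes a stationary tone and is stable in time", {
  fs <- 200
  t <- seq(0, 50 - 1 / fs, by = 1 / fs)
  seg <- make_segment(rbind(sin(2 * pi * 10 * t)), fs = fs)
  tf <- tf_wavelet(seg)
  expect_equal(ncol(tf$energy), 10)            # 50 s / 5 s
  ridge <- tf$freqs[apply(tf$energy, 2, which.max)]
  expect_true(all(abs(ridge - 10) / 10 < 0.15))
  peak_row <- which.max(rowMeans(tf$energy))
  cv <- sd(tf$energy[peak_row, ]) / mean(tf$energy[peak_row, ])
  expect_lt(cv, 0.05)
})

test_that("wavelet ridge follows a chirp monotonically", {
  fs <- 200
  dur <- 40
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  f0 <- 5; f1 <- 40
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)
  seg <- make_segment(rbind(sin(phase)), fs = fs)
  tf <- tf_wavelet(seg)
  ridge <- tf$freqs[apply(tf$energy, 2, which.max)]
  expect_true(all(diff(ridge) > 0))
  expect_error(tf_wavelet(make_segment(matrix(1.0, 1, 100), fs = fs)),
               "shorter")
})

test_that("total wavelet energy tracks broadband variance", {
  set.seed(60)
  fs <- 200
  r <- vapply(1:12, function(i) {
    amp <- runif(1, 0.5, 4)
    seg <- make_segment(rbind(amp * bl_noise(5 * fs, fs, 1, 50)), fs = fs)
    c(var(seg$samples[1, ]), sum(tf_wavelet(seg, window_s = 5)$energy))
  }, numeric(2))
  expect_gt(cor(r[1, ], r[2, ]), 0.95)
})

test_that("band energy ordering follows the 1/f-weighted synthesis", {
  cfg <- tiny_config(n_sessions = 4, seed = 12)
  rec <- generate_subject(cfg, 1)
  segs <- segment_sessions(rec)
  tf <- tf_wavelet(segs[[1]], window_s = 5)
  e <- rowMeans(tf$energy)
  band_mean <- function(lo, hi) mean(e[tf$freqs >= lo & tf$freqs < hi])
  bands <- eeg_bands()
  means <- mapply(band_mean, bands$lo, bands$hi)
  expect_true(all(diff(means) < 0))   # energy diminishes with frequency
})

test_that("baseline-subtracted topography cancels shared structure", {
  set.seed(61)
  fs <- 100
  m <- standard_montage()
  chans <- montage_channels(m)
  x <- matrix(rnorm(length(chans) * fs * 4), nrow = length(chans))
  seg <- make_segment(x, fs = fs, band = "gamma", channel_names = chans,
                      baseline = x[, 1:(2 * fs)])
  de <- de_features(list(seg))
  de_base <- de_features(list(seg), on = "baseline")
  # de computed on itself as baseline -> exact zeros
  tv0 <- topo_de(de, de)
  expect_true(all(abs(tv0$values) < 1e-12))
  # adding a constant to both tensors leaves the map unchanged
  tv1 <- topo_de(de, de_base)
  de2 <- de; de2$values <- de$values + 3
  db2 <- de_base; db2$values <- de_base$values + 3
  tv2 <- topo_de(de2, db2)
  expect_equal(tv1$values, tv2$values, tolerance = 1e-12)
  # axis mismatch errors
  bad <- de_base; bad$units <- rev(bad$units)
  expect_error(topo_de(de, bad), "axes")
})

test_that("scalp interpolation is exact at electrodes and symmetric", {
  m <- standard_montage()
  chans <- montage_channels(m)
  pos <- montage_positions(m, chans)
  vals <- matrix(0, length(chans), 1, dimnames = list(chans, "gamma"))
  # constant map stays constant
  tv <- structure(list(values = vals + 2.5, positions = pos,
                       bands = "gamma"), class = "topo_values")
  gc_ <- interpolate_scalp(tv, "gamma", grid_n = 31)
  expect_equal(range(gc_$z, na.rm = TRUE), c(2.5, 2.5), tolerance = 1e-5)
  # mirror-symmetric input gives a mirror-symmetric map
  set.seed(62)
  v <- abs(pos$y) + pos$x^2          # even in x
  tvs <- structure(list(values = matrix(v, ncol = 1,
                                        dimnames = list(chans, "gamma")),
                        positions = pos, bands = "gamma"),
                   class = "topo_values")
  g <- interpolate_scalp(tvs, "gamma", grid_n = 41)
  expect_equal(g$z, g$z[rev(seq_along(g$x)), ], tolerance = 1e-5)
  # electrode sites reproduce their values (nearest node of a fine grid)
  gg <- interpolate_scalp(tvs, "gamma", grid_n = 241)
  for (i in c(1, 5, 20, 40, 63)) {
    ii <- which.min(abs(gg$x - pos$x[i]))
    jj <- which.min(abs(gg$y - pos$y[i]))
    expect_lt(abs(gg$z[ii, jj] - v[i]), 0.05)   # within one grid cell
  }
  expect_error(interpolate_scalp(tvs, "sigma"), "unknown band")
})
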