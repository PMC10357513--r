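test_that("differential entropy matches the Gaussian closed form", {
  # unit-variance white windows: DE -> 0.5 * ln(2*pi*e) = 1.4189 nats
  set.seed(20)
  fs <- 200
  seg <- make_segment(matrix(rnorm(2 * 1000 * fs), nrow = 2), fs = fs,
                      band = "broad")
  de <- de_features(list(seg))
  expect_equal(dim(de$values), c(1000, 2, 1))
  expect_equal(mean(de$values), 0.5 * log(2 * pi * exp(1)), tolerance = 0.05)
})

test_that("doubling the amplitude raises DE by exactly ln 2", {
  set.seed(21)
  fs <- 200
  x <- matrix(rnorm(3 * 10 * fs), nrow = 3)
  d1 <- de_features(list(make_segment(x, fs = fs, band = "b")))
  d2 <- de_features(list(make_segment(2 * x, fs = fs, band = "b")))
  expect_equal(d2$values - d1$values,
               array(log(2), dim(d1$values)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("zero-variance windows hit the configurable floor and are flagged", {
  fs <- 100
  seg <- make_segment(matrix(0, 1, 3 * fs), fs = fs, band = "b")
  de <- de_features(list(seg), var_floor = 1e-10)
  expect_true(attr(de, "floored"))
  expect_equal(de$values[1, 1, 1], 0.5 * log(2 * pi * exp(1) * 1e-10))
})

test_that("STFT band energies localize a sinusoid in its band", {
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  seg <- make_segment(rbind(sin(2 * pi * 10 * t)), fs = fs)
  psd <- psd_features(seg)
  expect_equal(dim(psd$values), c(10, 1, 5))
  e <- colMeans(psd$values[, 1, ])
  expect_gt(e[["alpha"]], 10 * max(e[c("delta", "theta", "beta", "gamma")]))
  # zero signal -> all-zero PSD
  z <- psd_features(make_segment(matrix(0, 1, 5 * fs), fs = fs))
  expect_true(all(z$values == 0))
  # too-short segment -> empty tensor with warning
  expect_warning(short <- psd_features(make_segment(matrix(1.0, 1, 50), fs = fs)),
                 "shorter")
  expect_equal(dim(short$values)[1], 0)
})

test_that("DE equals log band energy up to an affine map (oracle route)", {
  set.seed(22)
  fs <- 200
  # stationary beta-band noise whose amplitude ramps smoothly over windows;
  # per-window values averaged over channels to expose the affine relation
  # above the two estimators' sampling noise
  n_win <- 100
  amps <- exp(seq(log(0.1), log(30), length.out = n_win))
  x <- do.call(rbind, lapply(1:6, function(c)
    unlist(lapply(amps, function(a) a * bl_noise(fs, fs, 14, 31)))))
  seg <- make_segment(x, fs = fs)
  b <- "beta"
  h <- rowMeans(de_features(seg)$values[, , b, drop = FALSE])
  logE <- rowMeans(log(psd_features(seg)$values[, , b, drop = FALSE]))
  expect_gt(summary(lm(h ~ logE))$r.squared, 0.99)
  # DE increases with band energy: (near-)perfect rank agreement
  expect_gt(cor(h, logE, method = "spearman"), 0.995)
})

test_that("DASM is the left-minus-right DE difference and antisymmetric", {
  set.seed(23)
  fs <- 200
  m <- standard_montage()
  chans <- montage_channels(m)
  pairs <- dasm_pairs(m)
  # mirrored scalp: left channel duplicates its right homolog
  x <- matrix(rnorm(length(chans) * fs * 4), nrow = length(chans))
  rownames(x) <- chans
  for (i in seq_len(nrow(pairs))) x[pairs$a[i], ] <- x[pairs$b[i], ]
  de <- de_features(list(make_segment(x, fs = fs, band = "b",
                                      channel_names = chans)))
  das <- dasm_features(de, pairs)
  expect_equal(dim(das$values)[2], 28)
  expect_true(all(abs(das$values) < 1e-12))
  # swapping a pair's channels negates its value
  y <- matrix(rnorm(length(chans) * fs * 2), nrow = length(chans))
  rownames(y) <- chans
  de_y <- de_features(list(make_segment(y, fs = fs, band = "b",
                                        channel_names = chans)))
  swapped <- pairs; swapped$a <- pairs$b; swapped$b <- pairs$a
  expect_equal(dasm_features(de_y, pairs)$values,
               -dasm_features(de_y, swapped)$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pair differences match hand-computed DE on a toy case", {
  fs <- 100
  set.seed(24)
  x <- rbind(3 * rnorm(fs * 2), 0.5 * rnorm(fs * 2))
  seg <- make_segment(x, fs = fs, band = "b", channel_names = c("Fp1", "O1"))
  de <- de_features(list(seg))
  pairs <- data.frame(a = "Fp1", b = "O1", kind = "frontal-posterior")
  dc <- dcau_features(de, pairs)
  v1 <- apply(matrix(x[1, ], nrow = fs), 2, var)
  v2 <- apply(matrix(x[2, ], nrow = fs), 2, var)
  expect_equal(dc$values[, 1, 1], 0.5 * log(v1 / v2), tolerance = 1e-12)
  # identical signals -> zero DCAU
  seg2 <- make_segment(rbind(x[1, ], x[1, ]), fs = fs, band = "b",
                       channel_names = c("Fp1", "O1"))
  dc2 <- dcau_features(de_features(list(seg2)), pairs)
  expect_true(all(abs(dc2$values) < 1e-12))
})

test_that("missing pair channels are dropped with a warning", {
  fs <- 100
  seg <- make_segment(matrix(rnorm(2 * fs * 2), 2), fs = fs, band = "b",
                      channel_names = c("AF3", "AF4"))
  de <- de_features(list(seg))
  expect_warning(das <- dasm_features(de), "dropping")
  expect_equal(das$units, "AF3-AF4")
})

test_that("feature extraction is permutation-equivariant in channels", {
  set.seed(25)
  fs <- 100
  x <- matrix(rnorm(4 * fs * 3), 4)
  chans <- c("a", "b", "c", "d")
  perm <- c(3, 1, 4, 2)
  de1 <- de_features(list(make_segment(x, fs = fs, band = "b",
                                       channel_names = chans)))
  de2 <- de_features(list(make_segment(x[perm, ], fs = fs, band = "b",
                                       channel_names = chans[perm])))
  expect_equal(de1$values[, perm, , drop = FALSE],
               de2$values[, , , drop = FALSE], ignore_attr = TRUE)
})

test_that("dataset assembly produces the documented column counts", {
  cfg <- tiny_config(n_sessions = 4)
  pre <- preprocess_chain(generate_subject(cfg, 1))
  segs <- segment_sessions(pre)
  sel <- which(vapply(segs, function(s) s$condition, "") == "haptic")
  usable <- montage_channels(standard_montage())
  des <- lapply(segs[sel], function(s)
    tensor_select_units(de_features(s), usable))
  labs <- vapply(segs[sel], function(s) s$emotion, "")
  ids <- vapply(segs[sel], function(s) s$session, 0L)
  # 63 channels per band, 63 x 5 = 315 for the all-band concatenation
  expect_equal(ncol(assemble_dataset(des, labs, ids, band = "gamma")$X), 63)
  expect_equal(ncol(assemble_dataset(des, labs, ids, band = "total")$X), 315)
  des64 <- lapply(segs[sel], de_features)      # with reconstructed FCz
  dasms <- lapply(des64, dasm_features)
  expect_equal(ncol(assemble_dataset(dasms, labs, ids, band = "total")$X), 140)
  dcaus <- lapply(des64, dcau_features)
  expect_equal(ncol(assemble_dataset(dcaus, labs, ids, band = "total")$X), 110)
  ds <- assemble_dataset(des, labs, ids, band = "gamma")
  expect_equal(nrow(ds$X), length(sel) * 8)    # 8 one-second windows per half
  expect_error(assemble_dataset(des, labs, ids, band = "sigma"), "band")
})
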