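test_that("experiment structure matches the protocol", {
  cfg <- tiny_config()
  rec <- generate_subject(cfg, 1)
  ann <- rec$annotations
  expect_equal(nrow(ann), 16)
  expect_equal(sum(ann$pattern == "haptic1"), 8)
  expect_equal(sum(ann$pattern == "haptic2"), 8)
  expect_equal(unname(table(ann$emotion)[c("joy", "sadness", "fear", "neutral")]),
               rep(4L, 4), ignore_attr = TRUE)
  # patterns balanced within each emotion
  for (e in unique(ann$emotion))
    expect_equal(sum(ann$pattern[ann$emotion == e] == "haptic1"), 2)
  # haptic onset at the clip midpoint, cue 5 s before the clip
  expect_equal(ann$haptic_onset_s, (ann$clip_onset_s + ann$clip_end_s) / 2)
  expect_equal(ann$clip_onset_s - ann$cue_onset_s, rep(5, 16))
  expect_equal(nrow(rec$samples), 63)
})

test_that("generation is bit-reproducible under the same seed", {
  cfg <- tiny_config(n_sessions = 4)
  r1 <- generate_subject(cfg, 1)
  r2 <- generate_subject(cfg, 1)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- generate_subject(tiny_config(n_sessions = 4, seed = 43), 1)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_sessions = 6), "divisible")
  expect_error(generator_config(haptic_gain = 0.5), "haptic_gain")
  expect_error(generator_config(base_power = c(delta = -1, theta = 1,
                                               alpha = 1, beta = 1,
                                               gamma = 1)), "positive")
  expect_error(generator_config(fs = 80), "sampling rate")
})

test_that("band synthesis confines variance to the configured band", {
  cfg <- tiny_config(
    n_sessions = 4,
    base_power = c(delta = 1e-8, theta = 1e-8, alpha = 1, beta = 1e-8,
                   gamma = 1e-8),
    profile = data.frame(emotion = character(), band = character(),
                         group = character(), mult = numeric()))
  rec <- generate_subject(cfg, 1)
  ratio <- band_power_ratio(rec$samples[10, ], rec$fs, 8, 14)
  expect_gt(ratio, 0.95)
})

test_that("unit haptic gain leaves the two halves exchangeable", {
  cfg <- tiny_config(haptic_gain = 1, seed = 77)
  rec <- generate_subject(cfg, 1)
  segs <- segment_sessions(rec)
  cond <- vapply(segs, function(s) s$condition, "")
  lv <- function(s) log(mean(apply(s$samples[1:10, ], 1, var)))
  d <- vapply(which(cond == "haptic"), function(i) lv(segs[[i]]), 0) -
    vapply(which(cond == "non-haptic"), function(i) lv(segs[[i]]), 0)
  # paired per-session log-variance ratios center on zero
  expect_gt(t.test(d)$p.value, 0.01)
})

test_that("class separation is confined to the configured bands and groups", {
  cfg <- tiny_config(seed = 5)
  rec <- generate_subject(cfg, 1)
  segs <- segment_sessions(rec)
  non <- segs[vapply(segs, function(s) s$condition, "") == "non-haptic"]
  emo <- vapply(non, function(s) s$emotion, "")
  grp <- channel_groups()
  band_var <- function(s, chans, lo, hi) {
    idx <- match(chans, s$channel_names)
    mean(vapply(idx, function(i)
      var(s$samples[i, ]) * band_power_ratio(s$samples[i, ], s$fs, lo, hi),
      0))
  }
  # temporal gamma power spreads across emotions...
  v_t <- vapply(non, band_var, 0, chans = grp$temporal, lo = 31, hi = 50)
  spread_informative <- diff(range(tapply(v_t, emo, mean))) /
    mean(tapply(v_t, emo, mean))
  # ...central delta power does not
  v_c <- vapply(non, band_var, 0, chans = grp$central, lo = 1, hi = 4)
  spread_null <- diff(range(tapply(v_c, emo, mean))) /
    mean(tapply(v_c, emo, mean))
  expect_gt(spread_informative, 3 * spread_null)
})

test_that("session haptic schedules realize both patterns", {
  cfg <- tiny_config()
  ann <- generate_subject(cfg, 1)$annotations
  for (i in seq_len(nrow(ann))) {
    sch <- session_haptic_schedule(ann[i, ], seed = 9)
    dur <- ann$clip_end_s[i] - ann$haptic_onset_s[i]
    if (nrow(sch)) {
      expect_true(all(sch$onset_s >= 0))
      expect_true(all(sch$onset_s + sch$duration_s <= dur + 1e-9))
      expect_true(all(sch$intensity >= 0 & sch$intensity <= 100))
    }
    if (ann$pattern[i] == "haptic1" && ann$emotion[i] != "neutral") {
      par <- haptic1_parameters()
      f <- par$frequency_hz[par$emotion == ann$emotion[i]]
      expect_equal(diff(sch$onset_s)[1], 1 / f, tolerance = 1e-9)
    }
    if (ann$pattern[i] == "haptic1" && ann$emotion[i] == "neutral")
      expect_equal(nrow(sch), 0)
  }
})
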