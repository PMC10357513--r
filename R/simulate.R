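#' Channel groups of the standard montage
#'
#' Partition of the 63 usable channels into scalp regions used by the
#' generator's band-power profile and by topography checks.
#'
#' @return Named list of character vectors covering every usable channel
#'   exactly once.
#' @export
channel_groups <- function() {
  list(
    prefrontal = c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8"),
    frontal = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
                "FC5", "FC3", "FC1", "FC2", "FC4", "FC6"),
    temporal = c("FT9", "FT7", "FT8", "FT10", "T7", "T8",
                 "TP9", "TP7", "TP8", "TP10", "C5", "C6"),
    central = c("C3", "C1", "Cz", "C2", "C4"),
    parietal = c("CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
                 "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    occipital = c("PO7", "PO3", "PO4", "PO8", "O1", "Oz", "O2", "CB1", "CB2"))
}

#' Default class-dependent band-power profile
#'
#' Emotion-discriminative amplitude multipliers per (emotion, band, channel
#' group). Cells absent from the table carry no class information. The
#' defaults concentrate the class signal in beta/gamma power of the lateral
#' temporal and prefrontal regions — joy activating temporal, sadness
#' prefrontal, fear intermediate, neutral inhibited — with a weaker alpha
#' effect over parietal channels, mirroring where emotion-related activation
#' is observed on the scalp.
#'
#' @return data.frame with columns `emotion`, `band`, `group`, `mult`.
#' @export
default_power_profile <- function() {
  g <- function(band, group, joy, sadness, fear, neutral)
    data.frame(emotion = c("joy", "sadness", "fear", "neutral"),
               band = band, group = group,
               mult = c(joy, sadness, fear, neutral))
  rbind(
    g("gamma", "temporal",   2.0, 0.7, 1.4, 0.3),
    g("gamma", "prefrontal", 0.7, 2.0, 1.3, 0.3),
    g("beta",  "temporal",   2.0, 0.8, 1.3, 0.35),
    g("beta",  "prefrontal", 1.0, 2.0, 0.6, 0.3),
    g("alpha", "parietal",   1.3, 0.7, 0.7, 1.3))
}

#' Generator configuration
#'
#' Assembles and validates the configuration of the synthetic experiment
#' generator. Defaults mirror the acquisition and protocol of the emulated
#' study: 63 usable channels at 1,000 Hz, 16 sessions of a 5-s cue followed
#' by a 4-min clip, four emotion classes balanced over sessions, both haptic
#' patterns presented for eight sessions, vibration confined to the second
#' half of each clip, 50 Hz line interference and frontal EOG-like blinks.
#' `clip_s`, `rest_s` and `fs` scale down for desk-size runs.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param n_sessions Sessions per subject; must be divisible by the number of
#'   emotions (default 16).
#' @param emotions Emotion labels (default joy, sadness, fear, neutral).
#' @param clip_s Clip duration in seconds (default 240).
#' @param cue_s Cue length before each clip in seconds (default 5, also the
#'   baseline window).
#' @param rest_s Self-assessment + rest gap after each clip (default 50).
#' @param fs Sampling rate in Hz (default 1000).
#' @param base_power Named per-band baseline variance (microvolt^2); the
#'   default decays with frequency.
#' @param disc_share Named per-band variance share of the discriminative
#'   component relative to `base_power`, in the profile's groups.
#' @param profile Class profile table as [default_power_profile()].
#' @param haptic_gain Multiplicative separation gain (>= 1) applied to the
#'   amplitude of discriminative components during the haptic half.
#' @param lateral_bias Named per-emotion hemispheric bias of the
#'   discriminative amplitude: left-hemisphere channels are scaled by
#'   `1 + bias/2`, right-hemisphere by `1 - bias/2` (midline unchanged).
#'   Positive = left-dominant. This valence-style lateralization is what
#'   gives left-right pair differences (DASM) their class information.
#' @param session_jitter_sd Standard deviation of the per-session,
#'   per-group-and-band log-amplitude jitter (session-to-session
#'   nonstationarity; limits cross-session generalization).
#' @param line_amp Amplitude (microvolts) of the 50 Hz line component.
#' @param line_freq Line frequency in Hz.
#' @param eog_amp Peak amplitude (microvolts) of frontal EOG-like blinks.
#' @param eog_rate Blink rate in events per second.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   experiments.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 16, n_sessions = 16,
                             emotions = c("joy", "sadness", "fear", "neutral"),
                             clip_s = 240, cue_s = 5, rest_s = 50, fs = 1000,
                             base_power = c(delta = 8, theta = 4, alpha = 2,
                                            beta = 1, gamma = 0.5),
                             disc_share = c(alpha = 0.25, beta = 0.5,
                                            gamma = 0.5),
                             profile = default_power_profile(),
                             haptic_gain = 2,
                             lateral_bias = c(joy = 0.4, sadness = -0.4,
                                              fear = 0.15, neutral = 0),
                             session_jitter_sd = 0.1,
                             line_amp = 2, line_freq = 50,
                             eog_amp = 80, eog_rate = 0.25, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions), emotions = emotions,
              clip_s = clip_s, cue_s = cue_s, rest_s = rest_s, fs = fs,
              base_power = base_power, disc_share = disc_share,
              profile = profile, haptic_gain = haptic_gain,
              lateral_bias = lateral_bias,
              session_jitter_sd = session_jitter_sd,
              line_amp = line_amp, line_freq = line_freq,
              eog_amp = eog_amp, eog_rate = eog_rate, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1) stop("n_subjects must be >= 1")
    if (n_sessions %% length(emotions) != 0)
      stop("n_sessions must be divisible by the number of emotions")
    if (clip_s <= 0 || cue_s <= 0 || rest_s < 0 || fs <= 0)
      stop("durations and sampling rate must be positive")
    if (haptic_gain < 1) stop("haptic_gain must be >= 1")
    if (any(base_power <= 0) || any(disc_share < 0))
      stop("band variances must be positive")
    if (!all(c("emotion", "band", "group", "mult") %in% names(profile)))
      stop("profile must have columns emotion, band, group, mult")
    bands <- eeg_bands()
    if (max(bands$hi) >= fs / 2)
      stop("sampling rate too low for the five-band decomposition")
  })
  invisible(cfg)
}

# unit-variance Gaussian noise confined to [lo, hi] Hz via FFT masking
bandlimited_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(freq, fs - freq)
  mask <- f_fold >= lo & f_fold <= hi
  x <- Re(stats::fft(W * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Hemisphere of a 10-20 channel label
#'
#' Odd-numbered labels are left-hemisphere, even-numbered right, unnumbered
#' (z-line) midline.
#' @param label A channel label such as `"F3"`, `"Cz"`, `"FT10"`.
#' @return `"left"`, `"right"` or `"mid"`.
#' @export
channel_hemisphere <- function(label) {
  num <- gsub("[^0-9]", "", label)
  if (num == "") return("mid")
  if (as.integer(num) %% 2 == 1) "left" else "right"
}

# smooth biphasic blink pulse, width ~0.4 s
blink_pulse <- function(fs) {
  t <- seq(-0.2, 0.2, by = 1 / fs)
  exp(-(t / 0.07)^2) - 0.35 * exp(-((t - 0.09) / 0.1)^2)
}

#' Session plan for one subject
#'
#' Balanced random session order (each emotion appears `n_sessions/4` times)
#' with the two haptic patterns split evenly within each emotion, which
#' implies the overall eight-sessions-per-pattern balance.
#'
#' @param cfg A `generator_config`.
#' @param subject_index 1-based subject index (fans the seed out).
#' @return data.frame with `session_id`, `emotion`, `pattern`.
#' @export
session_plan <- function(cfg, subject_index = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed * 1000L + subject_index)
  per <- cfg$n_sessions / length(cfg$emotions)
  emo <- rep(cfg$emotions, each = per)
  pat <- unlist(lapply(cfg$emotions, function(e)
    sample(rep(c("haptic1", "haptic2"), length.out = per))))
  ord <- sample.int(cfg$n_sessions)
  data.frame(session_id = seq_len(cfg$n_sessions),
             emotion = emo[ord], pattern = pat[ord])
}

#' Generate the synthetic recording of one subject
#'
#' Each channel is a sum over the five bands of band-limited Gaussian noise.
#' Baseline (cue/rest) variance per band follows `base_power` with a
#' per-session log-normal jitter shared within (channel group, band). During
#' the clip an independent discriminative component is added in the profile's
#' (band, group) cells with amplitude proportional to the session emotion's
#' multiplier; during the haptic second half that amplitude is multiplied by
#' `haptic_gain`. A fixed 50 Hz sinusoid and frontal EOG-like blink bursts
#' are superimposed.
#'
#' @param cfg A `generator_config`.
#' @param subject_index 1-based subject index.
#' @return An `eeg_recording` with 63 channels and one annotation row per
#'   session.
#' @export
generate_subject <- function(cfg, subject_index = 1L) {
  validate_generator_config(cfg)
  m <- standard_montage()
  chans <- montage_channels(m)
  groups <- channel_groups()
  group_of <- rep(NA_character_, length(chans))
  for (g in names(groups)) group_of[chans %in% groups[[g]]] <- g
  stopifnot(!anyNA(group_of))
  hemi_of <- vapply(chans, channel_hemisphere, "")
  bands <- eeg_bands()
  fs <- cfg$fs
  n_cue <- round(cfg$cue_s * fs)
  n_clip <- round(cfg$clip_s * fs)
  n_rest <- round(cfg$rest_s * fs)
  n_sess <- n_cue + n_clip + n_rest
  n_half <- floor(n_clip / 2)
  plan <- session_plan(cfg, subject_index)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed * 1000L + 500L + subject_index)

  X <- matrix(0, nrow = length(chans), ncol = n_sess * cfg$n_sessions)
  clip_env <- c(rep(0, n_cue), rep(1, n_half),
                rep(cfg$haptic_gain, n_clip - n_half), rep(0, n_rest))
  for (s in seq_len(cfg$n_sessions)) {
    emo <- plan$emotion[s]
    off <- (s - 1L) * n_sess
    for (b in seq_len(nrow(bands))) {
      bn <- bands$name[b]
      # session-level amplitude jitter shared within (group, band)
      jit <- stats::rnorm(length(groups), 0, cfg$session_jitter_sd)
      names(jit) <- names(groups)
      prof_b <- cfg$profile[cfg$profile$band == bn &
                              cfg$profile$emotion == emo, ]
      for (ci in seq_along(chans)) {
        g <- group_of[ci]
        v_base <- cfg$base_power[[bn]] * exp(jit[[g]])
        x <- sqrt(v_base) * bandlimited_noise(n_sess, fs, bands$lo[b], bands$hi[b])
        mult <- prof_b$mult[prof_b$group == g]
        if (length(mult) == 1 && !is.na(cfg$disc_share[bn]) &&
            cfg$disc_share[[bn]] > 0) {
          bias <- cfg$lateral_bias[[emo]]
          if (!is.null(bias) && hemi_of[[ci]] != "mid")
            mult <- mult * (1 + bias / 2 * if (hemi_of[[ci]] == "left") 1 else -1)
          v_disc <- cfg$base_power[[bn]] * cfg$disc_share[[bn]]
          x <- x + mult * sqrt(v_disc) * clip_env *
            bandlimited_noise(n_sess, fs, bands$lo[b], bands$hi[b])
        }
        X[ci, (off + 1):(off + n_sess)] <- X[ci, (off + 1):(off + n_sess)] + x
      }
    }
  }
  # 50 Hz line interference, random phase per channel
  if (cfg$line_amp > 0 && cfg$line_freq < fs / 2) {
    tt <- seq_len(ncol(X)) / fs
    ph <- stats::runif(length(chans), 0, 2 * pi)
    X <- X + cfg$line_amp *
      sin(outer(ph, 2 * pi * cfg$line_freq * tt, `+`))
  }
  # frontal EOG-like blink bursts
  if (cfg$eog_amp > 0 && cfg$eog_rate > 0) {
    w_eog <- stats::setNames(rep(0, length(chans)), chans)
    w_eog[chans %in% c("Fp1", "Fp2")] <- 1
    w_eog[chans %in% c("AF7", "AF3", "AF4", "AF8")] <- 0.6
    w_eog[chans %in% c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")] <- 0.2
    pulse <- blink_pulse(fs)
    n_blinks <- stats::rpois(1, cfg$eog_rate * ncol(X) / fs)
    if (n_blinks > 0) {
      onsets <- sort(sample.int(ncol(X) - length(pulse), n_blinks))
      eog <- numeric(ncol(X))
      for (o in onsets) {
        idx <- o:(o + length(pulse) - 1L)
        eog[idx] <- eog[idx] + pulse * cfg$eog_amp * stats::runif(1, 0.7, 1.3)
      }
      X <- X + w_eog %o% eog
    }
  }
  cue_on <- (seq_len(cfg$n_sessions) - 1L) * n_sess / fs
  ann <- session_annotations(plan$session_id, plan$emotion, plan$pattern,
                             cue_onset_s = cue_on,
                             clip_onset_s = cue_on + cfg$cue_s,
                             clip_end_s = cue_on + cfg$cue_s + cfg$clip_s)
  eeg_recording(X, fs, chans, ann, subject = sprintf("S%02d", subject_index))
}

#' Generate a complete synthetic experiment
#'
#' One recording per subject (see [generate_subject()]) plus the experiment
#' manifest. With the default configuration every subject has 16 annotated
#' sessions, four per emotion, and each haptic pattern is presented for
#' eight sessions.
#'
#' @param cfg A `generator_config`.
#' @return List with `recordings` (list of `eeg_recording`), `manifest`
#'   (data.frame over subjects x sessions) and `config`.
#' @export
generate_experiment <- function(cfg) {
  validate_generator_config(cfg)
  recs <- lapply(seq_len(cfg$n_subjects), function(i) generate_subject(cfg, i))
  manifest <- do.call(rbind, lapply(recs, function(r)
    cbind(subject = r$subject, r$annotations)))
  rownames(manifest) <- NULL
  list(recordings = recs, manifest = manifest, config = cfg)
}

#' Haptic schedule for one annotated session
#'
#' Pattern 1 sessions get the emotion's fixed-rhythm schedule (empty for
#' neutral, which has no pattern-1 parameters); pattern 2 sessions get the
#' volume-adaptive schedule driven by a seeded synthetic loudness trace.
#' Times are relative to the haptic onset (the clip midpoint).
#'
#' @param annotation One row of a [session_annotations()] table.
#' @param seed Seed for the pattern-2 volume trace.
#' @param threshold_quantile Silence threshold as a quantile of the trace.
#' @return A `haptic_schedule`.
#' @export
session_haptic_schedule <- function(annotation, seed = 1L,
                                    threshold_quantile = 0.3) {
  dur <- annotation$clip_end_s - annotation$haptic_onset_s
  if (annotation$pattern == "haptic1") {
    if (tolower(annotation$emotion) == "neutral")
      return(new_haptic_schedule(numeric(), numeric(), numeric()))
    haptic1_schedule(annotation$emotion, dur)
  } else {
    vol <- volume_trace(dur, seed = seed + annotation$session_id)
    thr <- stats::quantile(vol$samples, threshold_quantile, names = FALSE)
    haptic2_schedule(vol, threshold = thr)
  }
}
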