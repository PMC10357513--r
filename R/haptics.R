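#' Fixed-rhythm haptic pattern parameters
#'
#' Vibration frequency (pulse rhythm, Hz) and intensity (percent of motor
#' maximum) of the fixed haptic pattern for each non-neutral emotion:
#' joy 1.4 Hz at 90%, sadness 0.45 Hz at 50%, fear 0.5 Hz at 90%. Neutral
#' sessions receive no scheduled vibration under this pattern.
#'
#' @return data.frame with columns `emotion`, `frequency_hz`, `intensity`.
#' @export
haptic1_parameters <- function() {
  data.frame(emotion = c("joy", "sadness", "fear"),
             frequency_hz = c(1.4, 0.45, 0.5),
             intensity = c(90, 50, 90))
}

new_haptic_schedule <- function(onset_s, duration_s, intensity) {
  sch <- data.frame(onset_s = as.numeric(onset_s),
                    duration_s = as.numeric(duration_s),
                    intensity = as.numeric(intensity))
  if (nrow(sch)) {
    stopifnot(all(diff(sch$onset_s) > 0),
              all(sch$intensity >= 0 & sch$intensity <= 100),
              all(sch$onset_s[-1] >= (sch$onset_s + sch$duration_s)[-nrow(sch)]))
  }
  class(sch) <- c("haptic_schedule", "data.frame")
  sch
}

#' Fixed-rhythm (pattern 1) haptic schedule
#'
#' Discrete vibration pulses at the emotion's fixed frequency and intensity,
#' covering the whole stimulation interval.
#'
#' @param emotion One of `"joy"`, `"sadness"`, `"fear"`. Neutral has no
#'   defined pattern-1 parameters and raises an error.
#' @param duration_s Length of the stimulation interval in seconds.
#' @param pulse_s Duration of each discrete pulse in seconds; capped at half
#'   the pulse period so pulses never overlap.
#' @return A `haptic_schedule` data.frame with columns `onset_s`,
#'   `duration_s`, `intensity` (percent).
#' @examples
#' haptic1_schedule("joy", 10)   # 1.4 Hz pulses at 90% intensity
#' @export
haptic1_schedule <- function(emotion, duration_s, pulse_s = 0.2) {
  par <- haptic1_parameters()
  i <- match(tolower(emotion), par$emotion)
  if (is.na(i))
    stop("no fixed haptic pattern is defined for emotion '", emotion, "'")
  stopifnot(duration_s >= 0, pulse_s > 0)
  period <- 1 / par$frequency_hz[i]
  onsets <- seq(0, duration_s, by = period)
  onsets <- onsets[onsets < duration_s]
  if (!length(onsets)) return(new_haptic_schedule(numeric(), numeric(), numeric()))
  dur <- min(pulse_s, period / 2)
  dur <- pmin(dur, duration_s - onsets)
  new_haptic_schedule(onsets, dur, rep(par$intensity[i], length(onsets)))
}

#' Volume-to-intensity map of the adaptive (pattern 2) haptic schedule
#'
#' Below the silence threshold the intensity is 0 (no vibration); at and above
#' it, intensity is an affine, monotone nondecreasing map of loudness from
#' `i_min` at the threshold to `i_max` at the saturation volume `v_ref`,
#' clipped into \[i_min, i_max\].
#'
#' @param v Nonnegative loudness values.
#' @param threshold Silence threshold (same loudness units as `v`).
#' @param i_min,i_max Intensity range in percent, `i_min <= i_max`.
#' @param v_ref Loudness mapped to `i_max`; must exceed `threshold`.
#' @return Intensities in percent, same length as `v`.
#' @export
haptic2_intensity <- function(v, threshold, i_min = 30, i_max = 100,
                              v_ref = max(v)) {
  stopifnot(threshold >= 0, i_min <= i_max, all(v >= 0))
  if (v_ref <= threshold) v_ref <- threshold + .Machine$double.eps + threshold * 1e-9 + 1e-12
  raw <- i_min + (i_max - i_min) * (v - threshold) / (v_ref - threshold)
  out <- pmin(pmax(raw, i_min), i_max)
  out[v < threshold] <- 0
  out
}

#' Volume-adaptive (pattern 2) haptic schedule
#'
#' Converts a loudness trace of the stimulus soundtrack into vibration events:
#' samples below the silence threshold produce no vibration (this shapes the
#' rhythm), and louder passages vibrate with intensity positively related to
#' loudness via [haptic2_intensity()]. Contiguous supra-threshold runs are
#' merged into single events carrying their mean intensity.
#'
#' @param vol A `volume_trace` from [volume_trace()] (or a list with numeric
#'   `samples >= 0` and `rate` in Hz).
#' @param threshold Silence threshold.
#' @param i_min,i_max Intensity range in percent.
#' @param v_ref Saturation loudness, defaults to the trace maximum.
#' @return A `haptic_schedule` data.frame.
#' @export
haptic2_schedule <- function(vol, threshold, i_min = 30, i_max = 100,
                             v_ref = NULL) {
  stopifnot(is.list(vol), is.numeric(vol$samples), vol$rate > 0)
  v <- vol$samples
  if (!length(v)) return(new_haptic_schedule(numeric(), numeric(), numeric()))
  if (is.null(v_ref)) v_ref <- max(v)
  inten <- haptic2_intensity(v, threshold, i_min, i_max, v_ref)
  on <- inten > 0
  if (!any(on)) return(new_haptic_schedule(numeric(), numeric(), numeric()))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  dt <- 1 / vol$rate
  onset <- (starts[keep] - 1L) * dt
  dur <- r$lengths[keep] * dt
  mean_int <- mapply(function(s, e) mean(inten[s:e]), starts[keep], ends[keep])
  new_haptic_schedule(onset, dur, mean_int)
}

#' Synthetic soundtrack loudness trace
#'
#' Generates a smoothed nonnegative loudness envelope with occasional
#' silences, emulating the volume of a movie-clip soundtrack so that the
#' adaptive haptic pattern's silence-threshold rule is exercised.
#'
#' @param duration_s Trace length in seconds.
#' @param rate Sampling rate of the envelope in Hz (a coarse envelope rate,
#'   not an audio rate).
#' @param silence_prob Fraction of time spent in near-silence.
#' @param seed Optional integer seed for reproducibility.
#' @return A `volume_trace`: list with `samples` (nonnegative) and `rate`.
#' @export
volume_trace <- function(duration_s, rate = 10, silence_prob = 0.2,
                         seed = NULL) {
  stopifnot(duration_s >= 0, rate > 0, silence_prob >= 0, silence_prob < 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  n <- max(0L, as.integer(round(duration_s * rate)))
  if (n == 0L)
    return(structure(list(samples = numeric(), rate = rate),
                     class = "volume_trace"))
  x <- abs(stats::filter(stats::rnorm(n + 20), rep(1 / 8, 8), sides = 1))
  x <- as.numeric(x[-seq_len(20)])
  x[is.na(x)] <- 0
  # carve out silent stretches
  n_sil <- max(0L, as.integer(round(silence_prob * n / max(1, rate))))
  if (n_sil > 0) {
    for (k in seq_len(n_sil)) {
      s <- sample.int(n, 1L)
      e <- min(n, s + as.integer(rate))  # ~1 s silences
      x[s:e] <- x[s:e] * 0.01
    }
  }
  structure(list(samples = x, rate = rate), class = "volume_trace")
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
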