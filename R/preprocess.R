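#' Canonical five-band frequency decomposition
#'
#' delta 1-4 Hz, theta 4-8 Hz, alpha 8-14 Hz, beta 14-31 Hz, gamma 31-50 Hz.
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 14, 31),
             hi = c(4, 8, 14, 31, 50))
}

check_band <- function(lo, hi, fs) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("invalid corner frequencies [", lo, ", ", hi, "] Hz at fs = ", fs, " Hz")
}

# zero-phase Butterworth filtering along rows of a channels x time matrix
filt_matrix <- function(x, flt) {
  t(apply(x, 1, function(ch) signal::filtfilt(flt, ch)))
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase order-6 Butterworth low-pass at 0.45 x the target
#' rate, then keeps every `fs/fs_out`-th sample. Only integer decimation
#' factors are supported (1000 -> 200 Hz is the pipeline's standard use,
#' reducing the acquisition rate for computational economy).
#'
#' @param rec An `eeg_recording`.
#' @param fs_out Target sampling rate in Hz; must divide `rec$fs`.
#' @return The decimated `eeg_recording` (annotations carried over unchanged,
#'   they are stored in seconds).
#' @export
resample_recording <- function(rec, fs_out) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_out > rec$fs) stop("upsampling is not supported (fs_out > fs)")
  if (fs_out == rec$fs) return(rec)
  q <- rec$fs / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop("fs/fs_out must be an integer decimation factor, got ", q)
  q <- as.integer(round(q))
  lp <- signal::butter(6, 0.45 * fs_out / (rec$fs / 2), type = "low")
  y <- filt_matrix(rec$samples, lp)
  y <- y[, seq(1, ncol(y), by = q), drop = FALSE]
  eeg_recording(y, fs_out, rec$channel_names, rec$annotations, rec$subject)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward order-4 Butterworth band-pass, the pipeline's standard
#' 1-50 Hz analysis filter and per-band decomposition filter.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Corner frequencies in Hz, `0 < lo < hi < fs/2`.
#' @return Filtered `eeg_recording`.
#' @export
bandpass_recording <- function(rec, lo = 1, hi = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_band(lo, hi, rec$fs)
  bp <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  eeg_recording(filt_matrix(rec$samples, bp), rec$fs, rec$channel_names,
                rec$annotations, rec$subject)
}

#' Zero-phase notch filter for line interference
#'
#' Narrow band-stop (quality factor `q`, default 30) centred on the mains
#' frequency, applied forward-backward.
#'
#' @param rec An `eeg_recording`.
#' @param f0 Line frequency in Hz (50 by default).
#' @param q Quality factor; the stop band spans `f0/q` Hz.
#' @return Filtered `eeg_recording`.
#' @export
notch_recording <- function(rec, f0 = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"), f0 > 0, f0 < rec$fs / 2, q > 0)
  bw <- f0 / q
  bs <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (rec$fs / 2),
                       type = "stop")
  eeg_recording(filt_matrix(rec$samples, bs), rec$fs, rec$channel_names,
                rec$annotations, rec$subject)
}

#' Automated ICA-based ocular/muscular artifact removal
#'
#' Decomposes the recording with seeded FastICA, zeroes every independent
#' component whose absolute correlation with the frontal EOG proxy — the
#' low-passed (< 5 Hz) Fp1/Fp2 average, or the mean of the frontmost
#' channels present — exceeds `threshold`, and reconstructs the signal.
#' Low-passing makes the proxy specific to ocular activity, so band-limited
#' neural components at frontal sites are not rejected. The practice of
#' hand-picking components is replaced by this deterministic criterion.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @param seed Integer seed for the FastICA starting rotation.
#' @param threshold Absolute-correlation rejection threshold (default 0.8).
#' @param n_comp Number of components; defaults to the channel count.
#' @return The cleaned `eeg_recording`, with attribute `ica_removed` (indices
#'   of zeroed components) and `ica_converged` (logical). If FastICA fails to
#'   converge the input is returned unchanged with a warning and
#'   `ica_converged = FALSE`.
#' @export
remove_artifacts <- function(rec, seed = 1L, threshold = 0.8,
                             n_comp = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  if (nrow(x) < 2) stop("ICA requires at least 2 channels")
  if (is.null(n_comp)) n_comp <- nrow(x)
  eog <- frontal_reference(rec)
  dec <- fast_ica(x, n_comp = n_comp, seed = seed)
  if (!dec$converged) {
    warning("FastICA did not converge; returning recording unchanged")
    out <- rec
    attr(out, "ica_removed") <- integer()
    attr(out, "ica_converged") <- FALSE
    return(out)
  }
  cors <- abs(apply(dec$S, 1, function(s) stats::cor(s, eog)))
  cors[is.na(cors)] <- 0
  drop <- which(cors > threshold)
  S <- dec$S
  if (length(drop)) S[drop, ] <- 0
  y <- dec$A %*% S + dec$mean
  out <- eeg_recording(y, rec$fs, rec$channel_names, rec$annotations,
                       rec$subject)
  attr(out, "ica_removed") <- drop
  attr(out, "ica_converged") <- TRUE
  out
}

frontal_reference <- function(rec, lp_hz = 5) {
  front <- intersect(c("Fp1", "Fp2"), rec$channel_names)
  if (!length(front))
    front <- rec$channel_names[seq_len(min(2, length(rec$channel_names)))]
  proxy <- colMeans(rec$samples[front, , drop = FALSE])
  lp <- signal::butter(4, lp_hz / (rec$fs / 2), type = "low")
  signal::filtfilt(lp, proxy)
}

#' Common average re-referencing
#'
#' Subtracts, at every sample, the instantaneous mean over the usable data
#' channels, removing global background activity. When the recording was
#' acquired against the FCz reference (FCz absent from the channel list), the
#' FCz channel is recovered as the negated pre-average channel mean — the
#' standard reference-recovery identity — and appended, so that pair tables
#' involving FCz remain computable.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @param reconstruct_reference Append the recovered reference channel
#'   (default TRUE; skipped if a channel named FCz is already present).
#' @param reference_label Label of the recovered channel.
#' @return Re-referenced `eeg_recording`. The mean over the original usable
#'   channels is zero at every sample.
#' @export
rereference_car <- function(rec, reconstruct_reference = TRUE,
                            reference_label = "FCz") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2) stop("CAR requires at least 2 channels")
  has_ref <- toupper(reference_label) %in% toupper(rec$channel_names)
  usable <- rec$samples[!toupper(rec$channel_names) %in% toupper(reference_label), ,
                        drop = FALSE]
  m <- colMeans(usable)
  y <- sweep(rec$samples, 2, m)
  nm <- rec$channel_names
  if (reconstruct_reference && !has_ref) {
    y <- rbind(y, -m)
    nm <- c(nm, reference_label)
  }
  eeg_recording(y, rec$fs, nm, rec$annotations, rec$subject)
}

#' Cut a recording into per-session condition segments
#'
#' For each annotated session, extracts the 5-s pre-clip baseline and splits
#' the clip at its midpoint into the non-haptic first half and the haptic
#' second half (vibration was applied only during the second half), yielding
#' two `session_segment`s per session that share the same baseline.
#'
#' @param rec A preprocessed `eeg_recording` whose annotation times fall
#'   inside the recording.
#' @param annotations Annotation table; defaults to `rec$annotations`.
#' @param baseline_s Baseline length in seconds before clip onset (default 5).
#' @return List of `session_segment` objects, two per session.
#' @export
segment_sessions <- function(rec, annotations = rec$annotations,
                             baseline_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  n <- ncol(rec$samples)
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    i0 <- round(ann$clip_onset_s * fs)
    i1 <- round(ann$clip_end_s * fs)
    ib <- round((ann$clip_onset_s - baseline_s) * fs)
    if (ib < 0 || i1 > n)
      stop("session ", ann$session_id, " lies outside the recording")
    mid <- i0 + floor((i1 - i0) / 2)
    baseline <- rec$samples[, (ib + 1):i0, drop = FALSE]
    halves <- list(
      `non-haptic` = rec$samples[, (i0 + 1):mid, drop = FALSE],
      haptic = rec$samples[, (mid + 1):i1, drop = FALSE])
    for (cond in names(halves)) {
      out[[length(out) + 1L]] <- structure(
        list(samples = halves[[cond]], fs = fs,
             channel_names = rec$channel_names,
             subject = rec$subject, session = ann$session_id,
             emotion = ann$emotion, pattern = ann$pattern,
             condition = cond, baseline = baseline),
        class = "session_segment")
    }
  }
  out
}

#' @export
print.session_segment <- function(x, ...) {
  cat(sprintf("<session_segment> %s s%02d %s/%s/%s: %d ch x %d samples @ %g Hz\n",
              x$subject, x$session, x$emotion, x$pattern, x$condition,
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

#' Decompose a segment into frequency bands
#'
#' One zero-phase order-4 Butterworth band-pass copy of the segment per band.
#' The baseline is decomposed alongside the segment so baseline features can
#' be computed in the same bands.
#'
#' @param seg A `session_segment`.
#' @param bands Band table as from [eeg_bands()].
#' @return Named list of band-filtered `session_segment`s (each gains a
#'   `band` field).
#' @export
band_decompose <- function(seg, bands = eeg_bands()) {
  stopifnot(inherits(seg, "session_segment"))
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    check_band(bands$lo[i], bands$hi[i], seg$fs)
    bp <- signal::butter(4, c(bands$lo[i], bands$hi[i]) / (seg$fs / 2),
                         type = "pass")
    s2 <- seg
    s2$samples <- filt_matrix(seg$samples, bp)
    rownames(s2$samples) <- seg$channel_names
    s2$baseline <- filt_matrix(seg$baseline, bp)
    rownames(s2$baseline) <- seg$channel_names
    s2$band <- bands$name[i]
    out[[i]] <- s2
  }
  out
}

#' Standard preprocessing chain for one recording
#'
#' Runs the documented order: decimation to `fs_target`, 50 Hz notch,
#' 1-50 Hz zero-phase band-pass, optional seeded ICA artifact removal, and
#' common average re-referencing with reference recovery.
#' [preprocess_recording()] additionally segments the result into
#' per-session condition halves.
#'
#' @param rec Raw `eeg_recording`.
#' @param fs_target Analysis rate in Hz (default 200).
#' @param notch Line frequency to notch out after decimation (default 50 Hz;
#'   `NULL` to skip).
#' @param ica Run the ICA stage (default FALSE: the synthetic generator's
#'   artifacts are optional and the stage is costly at 63 channels).
#' @param ica_seed,ica_threshold Passed to [remove_artifacts()].
#' @return `preprocess_chain`: the preprocessed `eeg_recording`.
#' @export
preprocess_chain <- function(rec, fs_target = 200, notch = 50, ica = FALSE,
                             ica_seed = 1L, ica_threshold = 0.8) {
  rec <- resample_recording(rec, fs_target)
  if (!is.null(notch)) rec <- notch_recording(rec, notch)
  rec <- bandpass_recording(rec, 1, 50)
  if (ica) rec <- remove_artifacts(rec, seed = ica_seed,
                                   threshold = ica_threshold)
  rereference_car(rec)
}

#' @rdname preprocess_chain
#' @param baseline_s Baseline window in seconds.
#' @return `preprocess_recording`: list of `session_segment`s.
#' @export
preprocess_recording <- function(rec, fs_target = 200, notch = 50,
                                 ica = FALSE, ica_seed = 1L,
                                 ica_threshold = 0.8, baseline_s = 5) {
  rec <- preprocess_chain(rec, fs_target = fs_target, notch = notch,
                          ica = ica, ica_seed = ica_seed,
                          ica_threshold = ica_threshold)
  segment_sessions(rec, baseline_s = baseline_s)
}

#' Band-decompose a whole recording
#'
#' One zero-phase band-filtered copy of the recording per band; filtering the
#' continuous recording once per band (rather than each segment separately)
#' is substantially cheaper and avoids per-segment edge transients.
#'
#' @param rec An `eeg_recording`.
#' @param bands Band table as from [eeg_bands()].
#' @return Named list of band-filtered `eeg_recording`s.
#' @export
band_decompose_recording <- function(rec, bands = eeg_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    check_band(bands$lo[i], bands$hi[i], rec$fs)
    bp <- signal::butter(4, c(bands$lo[i], bands$hi[i]) / (rec$fs / 2),
                         type = "pass")
    out[[i]] <- eeg_recording(filt_matrix(rec$samples, bp), rec$fs,
                              rec$channel_names, rec$annotations, rec$subject)
  }
  out
}
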