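#' Construct a raw multichannel EEG recording
#'
#' @param samples channels x time numeric matrix (microvolts); row names, if
#'   set, must agree with `channel_names`.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one label per row of `samples`.
#' @param annotations data.frame of session annotations (see
#'   [session_annotations()]); may be empty.
#' @param subject Subject identifier.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, fs, channel_names,
                          annotations = empty_annotations(), subject = "S01") {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), fs > 0,
            length(channel_names) == nrow(samples),
            !anyDuplicated(channel_names))
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs,
                 channel_names = as.character(channel_names),
                 annotations = annotations, subject = subject),
            class = "eeg_recording")
}

empty_annotations <- function() {
  data.frame(session_id = integer(), emotion = character(),
             pattern = character(), cue_onset_s = numeric(),
             clip_onset_s = numeric(), haptic_onset_s = numeric(),
             clip_end_s = numeric())
}

#' Session annotation table
#'
#' One row per session: the emotion label, the assigned haptic pattern, and
#' the event times. The haptic onset sits at the clip midpoint (vibration is
#' confined to the second half of each clip) and the cue precedes the clip by
#' the cue length.
#'
#' @param session_id Integer ids.
#' @param emotion Emotion label per session.
#' @param pattern `"haptic1"` or `"haptic2"` per session.
#' @param cue_onset_s,clip_onset_s,clip_end_s Event times in seconds.
#' @return data.frame of class `session_annotations`.
#' @export
session_annotations <- function(session_id, emotion, pattern,
                                cue_onset_s, clip_onset_s, clip_end_s) {
  stopifnot(all(clip_onset_s > cue_onset_s), all(clip_end_s > clip_onset_s))
  ann <- data.frame(session_id = as.integer(session_id),
                    emotion = as.character(emotion),
                    pattern = as.character(pattern),
                    cue_onset_s = cue_onset_s,
                    clip_onset_s = clip_onset_s,
                    haptic_onset_s = (clip_onset_s + clip_end_s) / 2,
                    clip_end_s = clip_end_s)
  class(ann) <- c("session_annotations", "data.frame")
  ann
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz, %d annotated sessions\n",
              x$subject, nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs
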