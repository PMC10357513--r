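# serialize one annotation row to a marker description and back
ann_to_text <- function(ann) {
  sprintf("session:%d|emotion:%s|pattern:%s|cue:%s|clip_on:%s|clip_end:%s",
          ann$session_id, ann$emotion, ann$pattern,
          format(ann$cue_onset_s, digits = 15),
          format(ann$clip_onset_s, digits = 15),
          format(ann$clip_end_s, digits = 15))
}

text_to_ann <- function(txt) {
  fields <- strsplit(strsplit(txt, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  kv <- stats::setNames(vapply(fields, `[`, "", 2), vapply(fields, `[`, "", 1))
  data.frame(session_id = as.integer(kv[["session"]]),
             emotion = kv[["emotion"]], pattern = kv[["pattern"]],
             cue_onset_s = as.numeric(kv[["cue"]]),
             clip_onset_s = as.numeric(kv[["clip_on"]]),
             clip_end_s = as.numeric(kv[["clip_end"]]))
}

anns_from_texts <- function(txts) {
  if (!length(txts)) return(empty_annotations())
  tab <- do.call(rbind, lapply(txts, text_to_ann))
  session_annotations(tab$session_id, tab$emotion, tab$pattern,
                      tab$cue_onset_s, tab$clip_onset_s, tab$clip_end_s)
}

#' Write a recording to disk
#'
#' Supported formats: BrainVision (a `.vhdr`/`.vmrk`/`.eeg` triplet with
#' IEEE float-32 multiplexed data; annotations become markers) and EDF+
#' (16-bit samples with per-channel physical scaling and an EDF annotations
#' signal; read-back reproduces samples within the 16-bit quantization
#' step). EDF recordings are padded with zeros to a whole number of 1-s data
#' records.
#'
#' @param rec An `eeg_recording` with finite samples.
#' @param path Output path without extension (BrainVision) or with `.edf`
#'   (EDF; appended if missing).
#' @param format `"BrainVision"` or `"EDF"`.
#' @return Invisibly, the written file path(s).
#' @export
write_recording <- function(rec, path, format = c("BrainVision", "EDF")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "BrainVision") write_brainvision(rec, path)
  else write_edf(rec, path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path `.vhdr` path (BrainVision) or `.edf` path.
#' @param subject Subject id to attach.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, subject = "S01") {
  if (grepl("\\.vhdr$", path)) read_brainvision(path, subject)
  else if (grepl("\\.edf$", path)) read_edf(path, subject)
  else stop("unsupported recording format: ", path)
}

# ---- BrainVision ------------------------------------------------------------

write_brainvision <- function(rec, path) {
  base <- sub("\\.vhdr$", "", path)
  stem <- basename(base)
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$samples)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 15)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$samples)),
            rec$channel_names))
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", "Codepage=UTF-8",
          paste0("DataFile=", stem, ".eeg"),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000")
  if (nrow(rec$annotations)) {
    pos <- round(rec$annotations$cue_onset_s * rec$fs) + 1L
    mk <- c(mk, sprintf("Mk%d=Annotation,%s,%d,1,0",
                        seq_len(nrow(rec$annotations)) + 1L,
                        vapply(seq_len(nrow(rec$annotations)), function(i)
                          ann_to_text(rec$annotations[i, ]), ""),
                        pos))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb"); on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4, endian = "little")
  invisible(c(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

bv_field <- function(lines, key) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (!length(hit)) stop("missing BrainVision field ", key)
  sub(paste0("^", key, "="), "", hit[1])
}

read_brainvision <- function(vhdr, subject = "S01") {
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  nch <- as.integer(bv_field(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(bv_field(lines, "SamplingInterval"))
  fmt <- bv_field(lines, "BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") stop("unsupported BinaryFormat ", fmt)
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  chans <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE),
                  `[`, "", 1)
  base <- sub("\\.vhdr$", "", vhdr)
  eeg <- paste0(base, ".eeg"); vmrk <- paste0(base, ".vmrk")
  n_bytes <- file.info(eeg)$size
  con <- file(eeg, "rb")
  raw <- readBin(con, "numeric", n = n_bytes / 4, size = 4, endian = "little")
  close(con)
  x <- matrix(raw, nrow = nch)
  ann <- empty_annotations()
  if (file.exists(vmrk)) {
    mls <- grep("^Mk[0-9]+=Annotation,", readLines(vmrk, warn = FALSE),
                value = TRUE)
    if (length(mls)) {
      txts <- vapply(strsplit(sub("^Mk[0-9]+=Annotation,", "", mls), ",",
                              fixed = TRUE), `[`, "", 1)
      ann <- anns_from_texts(txts)
    }
  }
  eeg_recording(x, fs, chans, ann, subject)
}

# ---- EDF+ -------------------------------------------------------------------

edf_pad <- function(s, n) {
  s <- substr(paste0(s, strrep(" ", n)), 1, n)
  s
}

edf_num <- function(x, n) edf_pad(format(x, trim = TRUE, digits = 8,
                                         scientific = FALSE), n)

write_edf <- function(rec, path) {
  if (!grepl("\\.edf$", path)) path <- paste0(path, ".edf")
  x <- rec$samples
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(x)
  n_rec <- ceiling(ncol(x) / fs)
  if (ncol(x) < n_rec * fs)
    x <- cbind(x, matrix(0, nch, n_rec * fs - ncol(x)))
  # physical scaling per channel
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  # annotation TALs, one list of texts per record
  tal_rec <- function(r) {
    ts <- sprintf("+%s\x14\x14", format((r - 1), trim = TRUE))
    anns <- rec$annotations
    if (nrow(anns)) {
      sel <- which(floor(anns$cue_onset_s) == (r - 1))
      for (i in sel)
        ts <- paste0(ts, sprintf("+%s\x14%s\x14",
                                 format(anns$cue_onset_s[i], digits = 15),
                                 ann_to_text(anns[i, ])))
    }
    ts
  }
  tals <- vapply(seq_len(n_rec), tal_rec, "")
  ann_bytes <- max(nchar(tals, type = "bytes")) + 2
  ann_samples <- ceiling(ann_bytes / 2)
  ns <- nch + 1L
  hdr_bytes <- 256L + 256L * ns
  con <- file(path, "wb"); on.exit(close(con))
  put <- function(s, n) writeBin(charToRaw(edf_pad(s, n)), con)
  put("0", 8); put("X X X X", 80); put("Startdate 01-JAN-2000 X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(format(hdr_bytes), 8); put("EDF+C", 44)
  put(format(n_rec), 8); put("1", 8); put(format(ns), 4)
  labs <- c(rec$channel_names, "EDF Annotations")
  for (l in labs) put(l, 16)
  for (i in seq_len(ns)) put("", 80)                      # transducer
  for (i in seq_len(ns)) put(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) put(if (i <= nch) edf_num(pmin_[i], 8) else "-1", 8)
  for (i in seq_len(ns)) put(if (i <= nch) edf_num(pmax_[i], 8) else "1", 8)
  for (i in seq_len(ns)) put(format(dmin), 8)
  for (i in seq_len(ns)) put(format(dmax), 8)
  for (i in seq_len(ns)) put("", 80)                      # prefilter
  for (i in seq_len(ns)) put(format(if (i <= nch) fs else ann_samples), 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (c in seq_len(nch)) {
      dig <- round((x[c, idx] - pmin_[c]) * scale[c]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
    tal <- charToRaw(tals[r])
    writeBin(c(tal, raw(2 * ann_samples - length(tal))), con)
  }
  invisible(path)
}

read_edf <- function(path, subject = "S01") {
  con <- file(path, "rb"); on.exit(close(con))
  get <- function(n) rawToChar(readBin(con, "raw", n))
  trimws(get(8)); get(80); get(80); get(8); get(8)
  hdr_bytes <- as.integer(trimws(get(8))); get(44)
  n_rec <- as.integer(trimws(get(8)))
  rec_dur <- as.numeric(trimws(get(8)))
  ns <- as.integer(trimws(get(4)))
  labs <- trimws(vapply(seq_len(ns), function(i) get(16), ""))
  for (i in seq_len(ns)) get(80)
  for (i in seq_len(ns)) get(8)
  pmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) get(8), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) get(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(ns), function(i) get(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(ns), function(i) get(8), "")))
  for (i in seq_len(ns)) get(80)
  nspr <- as.integer(trimws(vapply(seq_len(ns), function(i) get(8), "")))
  for (i in seq_len(ns)) get(32)
  is_ann <- labs == "EDF Annotations"
  sig_idx <- which(!is_ann)
  fs <- nspr[sig_idx[1]] / rec_dur
  x <- matrix(0, length(sig_idx), n_rec * nspr[sig_idx[1]])
  ann_txt <- character()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        bytes <- readBin(con, "raw", 2 * nspr[s])
        txt <- rawToChar(bytes[bytes != as.raw(0)])
        ann_txt <- c(ann_txt, txt)
      } else {
        dig <- readBin(con, "integer", nspr[s], size = 2, endian = "little")
        phys <- pmin_[s] + (dig - dmin[s]) * (pmax_[s] - pmin_[s]) /
          (dmax[s] - dmin[s])
        ci <- match(s, sig_idx)
        x[ci, ((r - 1) * nspr[s] + 1):(r * nspr[s])] <- phys
      }
    }
  }
  # parse annotation texts out of the TALs (skip bare timestamps)
  txts <- unlist(lapply(ann_txt, function(t) {
    tals <- strsplit(t, "\x14\x14|\x14", fixed = FALSE)[[1]]
    grep("^session:", tals, value = TRUE)
  }))
  eeg_recording(x, fs, labs[sig_idx], anns_from_texts(txts), subject)
}

#' Write / read the experiment manifest
#'
#' The manifest lists, per subject and session, the emotion label, the
#' assigned haptic pattern, and the event onsets, as plain CSV.
#'
#' @param manifest data.frame as produced by [generate_experiment()].
#' @param path CSV path.
#' @return `write_manifest` invisibly returns `path`; `read_manifest` the
#'   data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
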