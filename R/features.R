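new_feature_tensor <- function(kind, values, units, bands, window_s = 1) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[2] == length(units),
            dim(values)[3] == length(bands))
  dimnames(values) <- list(NULL, units, bands)
  structure(list(kind = kind, values = values, units = units,
                 bands = bands, window_s = window_s),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %s: %d windows x %d units x %d bands (%g-s windows)\n",
              x$kind, d[1], d[2], d[3], x$window_s))
  invisible(x)
}

# split a channels x time matrix into non-overlapping windows of n samples
window_starts <- function(n_time, n_win) {
  n <- floor(n_time / n_win)
  if (n == 0) integer() else (seq_len(n) - 1L) * n_win + 1L
}

# sample variance (n-1 denominator) of each channel in each non-overlapping
# window: channels x n_windows matrix, vectorized via an indicator product
window_var <- function(x, n_win) {
  W <- floor(ncol(x) / n_win)
  if (W == 0) return(matrix(0, nrow(x), 0))
  xs <- x[, seq_len(W * n_win), drop = FALSE]
  ind <- matrix(0, W * n_win, W)
  ind[cbind(seq_len(W * n_win), rep(seq_len(W), each = n_win))] <- 1
  s1 <- xs %*% ind
  s2 <- xs^2 %*% ind
  (s2 - s1^2 / n_win) / (n_win - 1)
}

#' Short-time Fourier band-power (PSD) features
#'
#' Per non-overlapping 1-s window, per channel, per band: the mean spectral
#' energy over the band's frequency bins of a 256-point FFT of the
#' Hanning-tapered window (200 samples at the 200 Hz analysis rate,
#' zero-padded to 256). Band bins are `lo <= f < hi`.
#'
#' @param seg A broadband `session_segment` (no band decomposition needed;
#'   band energies are read off the spectrum).
#' @param bands Band table as [eeg_bands()].
#' @param window_s Window length in seconds (default 1).
#' @param nfft FFT length (default 256).
#' @return A `feature_tensor` of kind `"PSD"`. A segment shorter than one
#'   window yields an empty tensor with a warning.
#' @export
psd_features <- function(seg, bands = eeg_bands(), window_s = 1, nfft = 256) {
  stopifnot(inherits(seg, "session_segment"))
  psd_matrix(seg$samples, seg$fs, seg$channel_names, bands, window_s, nfft)
}

psd_matrix <- function(x, fs, channel_names, bands = eeg_bands(),
                       window_s = 1, nfft = 256) {
  n_win <- round(window_s * fs)
  stopifnot(nfft >= n_win)
  starts <- window_starts(ncol(x), n_win)
  if (!length(starts)) {
    warning("segment shorter than one window; returning empty tensor")
    return(new_feature_tensor("PSD",
                              array(0, c(0, nrow(x), nrow(bands))),
                              channel_names, bands$name, window_s))
  }
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, n_win - 1) / (n_win - 1)))
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  bin_sets <- lapply(seq_len(nrow(bands)), function(b)
    which(freq >= bands$lo[b] & freq < bands$hi[b]))
  vals <- array(0, c(length(starts), nrow(x), nrow(bands)))
  for (w in seq_along(starts)) {
    seg_w <- x[, starts[w]:(starts[w] + n_win - 1L), drop = FALSE]
    xt <- sweep(seg_w, 2, taper, `*`)
    spec <- Mod(stats::mvfft(t(cbind(xt, matrix(0, nrow(x), nfft - n_win)))))^2
    spec <- t(spec[seq_along(freq), , drop = FALSE])  # channels x bins
    for (b in seq_len(nrow(bands)))
      vals[w, , b] <- rowMeans(spec[, bin_sets[[b]], drop = FALSE])
  }
  new_feature_tensor("PSD", vals, channel_names, bands$name, window_s)
}

#' Differential entropy (DE) features
#'
#' Per non-overlapping 1-s window, per channel, per band: the Gaussian
#' differential entropy `0.5 * ln(2 * pi * e * var)` in nats, where `var` is
#' the sample variance of the band-filtered window. For a band-limited
#' Gaussian signal this equals the logarithmic spectral energy up to an
#' additive constant.
#'
#' @param seg A `session_segment` (decomposed internally with
#'   [band_decompose()]) or a list of band-filtered segments as produced by
#'   [band_decompose()].
#' @param bands Band table (ignored when `seg` is already decomposed).
#' @param window_s Window length in seconds (default 1).
#' @param var_floor Variance floor substituted for zero-variance windows
#'   (flagged via the `floored` attribute).
#' @param on What to compute features on: the segment `"samples"` or its
#'   pre-stimulus `"baseline"`.
#' @return A `feature_tensor` of kind `"DE"` (values in nats).
#' @export
de_features <- function(seg, bands = eeg_bands(), window_s = 1,
                        var_floor = 1e-12, on = c("samples", "baseline")) {
  on <- match.arg(on)
  if (inherits(seg, "session_segment")) seg <- band_decompose(seg, bands)
  stopifnot(is.list(seg), length(seg) >= 1,
            all(vapply(seg, inherits, TRUE, "session_segment")))
  fs <- seg[[1]]$fs
  n_win <- round(window_s * fs)
  chans <- seg[[1]]$channel_names
  band_names <- vapply(seg, function(s) s$band, "")
  get_x <- function(s) if (on == "samples") s$samples else s$baseline
  starts <- window_starts(ncol(get_x(seg[[1]])), n_win)
  if (!length(starts)) {
    warning("segment shorter than one window; returning empty tensor")
    return(new_feature_tensor("DE", array(0, c(0, length(chans), length(seg))),
                              chans, band_names, window_s))
  }
  vals <- array(0, c(length(starts), length(chans), length(seg)))
  floored <- FALSE
  for (b in seq_along(seg)) {
    v <- window_var(get_x(seg[[b]]), n_win)     # channels x windows
    if (any(v <= var_floor)) { floored <- TRUE; v <- pmax(v, var_floor) }
    vals[, , b] <- t(0.5 * log(2 * pi * exp(1) * v))
  }
  out <- new_feature_tensor("DE", vals, chans, band_names, window_s)
  attr(out, "floored") <- floored
  out
}

#' Subset a feature tensor to selected units
#'
#' Used e.g. to restrict channel-wise tensors to the montage's 63 usable
#' channels after the reconstructed reference has served the pair tables.
#'
#' @param tensor A `feature_tensor`.
#' @param units Unit labels to keep (matched case-insensitively), in the
#'   requested order.
#' @return The subset `feature_tensor`.
#' @export
tensor_select_units <- function(tensor, units) {
  stopifnot(inherits(tensor, "feature_tensor"))
  idx <- match(toupper(units), toupper(tensor$units))
  if (anyNA(idx))
    stop("unknown unit(s): ", paste(units[is.na(idx)], collapse = ", "))
  new_feature_tensor(tensor$kind,
                     tensor$values[, idx, , drop = FALSE],
                     tensor$units[idx], tensor$bands, tensor$window_s)
}

pair_difference <- function(de, pairs, kind) {
  stopifnot(inherits(de, "feature_tensor"), de$kind == "DE")
  ia <- match(toupper(pairs$a), toupper(de$units))
  ib <- match(toupper(pairs$b), toupper(de$units))
  ok <- !(is.na(ia) | is.na(ib))
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " ", kind,
            " pair(s) with channels absent from the tensor: ",
            paste(paste0(pairs$a[!ok], "-", pairs$b[!ok]), collapse = ", "))
    pairs <- pairs[ok, ]; ia <- ia[ok]; ib <- ib[ok]
  }
  if (!nrow(pairs)) stop("no resolvable ", kind, " pairs")
  vals <- de$values[, ia, , drop = FALSE] - de$values[, ib, , drop = FALSE]
  new_feature_tensor(kind, vals, paste0(pairs$a, "-", pairs$b), de$bands,
                     de$window_s)
}

#' Hemispheric-asymmetry (DASM) features
#'
#' Left-minus-right differential entropy over the 28 homologous electrode
#' pairs: `DASM = h(left) - h(right)` per window and band.
#'
#' @param de A `feature_tensor` of kind `"DE"` with channel units.
#' @param pairs Pair table from [dasm_pairs()].
#' @return A `feature_tensor` of kind `"DASM"` (28 units). Pairs whose
#'   channels are missing are dropped with a warning.
#' @export
dasm_features <- function(de, pairs = dasm_pairs()) {
  pair_difference(de, pairs, "DASM")
}

#' Frontal-posterior (DCAU) features
#'
#' Frontal-minus-posterior differential entropy over the 22 caudality pairs:
#' `DCAU = h(frontal) - h(posterior)` per window and band.
#'
#' @param de A `feature_tensor` of kind `"DE"` with channel units.
#' @param pairs Pair table from [dcau_pairs()].
#' @return A `feature_tensor` of kind `"DCAU"` (22 units).
#' @export
dcau_features <- function(de, pairs = dcau_pairs()) {
  pair_difference(de, pairs, "DCAU")
}

#' Assemble a classification dataset from per-session feature tensors
#'
#' One row per 1-s window; columns are the tensor units for a single band, or
#' the concatenation of all band slices for `band = "total"` (e.g. 63 x 5 =
#' 315 columns for channel-wise DE). Rows are tagged with their session id so
#' cross-validation can fold whole sessions.
#'
#' @param tensors List of `feature_tensor`s of one kind, one per session.
#' @param labels Emotion label per tensor.
#' @param sessions Session id per tensor.
#' @param band One band name or `"total"`.
#' @return A `feature_dataset`: list with matrix `X`, factor `y`, vector
#'   `groups`, and `band`.
#' @export
assemble_dataset <- function(tensors, labels, sessions, band = "total") {
  stopifnot(length(tensors) == length(labels),
            length(tensors) == length(sessions), length(tensors) >= 1)
  kinds <- unique(vapply(tensors, function(t) t$kind, ""))
  if (length(kinds) != 1) stop("tensors mix feature kinds: ",
                               paste(kinds, collapse = ", "))
  rows <- list(); y <- character(); grp <- c()
  for (i in seq_along(tensors)) {
    tn <- tensors[[i]]
    if (band == "total") {
      X <- do.call(cbind, lapply(seq_along(tn$bands), function(b) {
        m <- tn$values[, , b, drop = FALSE]
        dim(m) <- dim(tn$values)[1:2]
        colnames(m) <- paste0(tn$units, ".", tn$bands[b])
        m
      }))
    } else {
      b <- match(band, tn$bands)
      if (is.na(b)) stop("band '", band, "' not present in tensor")
      X <- tn$values[, , b, drop = FALSE]
      dim(X) <- dim(tn$values)[1:2]
      colnames(X) <- tn$units
    }
    if (!nrow(X)) next
    rows[[length(rows) + 1L]] <- X
    y <- c(y, rep(labels[i], nrow(X)))
    grp <- c(grp, rep(sessions[i], nrow(X)))
  }
  if (!length(rows)) stop("no windows available to assemble")
  ncols <- unique(vapply(rows, ncol, 0L))
  if (length(ncols) != 1) stop("inconsistent feature dimensions across sessions")
  X <- do.call(rbind, rows)
  if (!all(is.finite(X))) stop("non-finite feature values")
  structure(list(X = X, y = factor(y), groups = grp, band = band,
                 kind = kinds),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %s/%s: %d windows x %d features, %d sessions, %d classes\n",
              x$kind, x$band, nrow(x$X), ncol(x$X),
              length(unique(x$groups)), nlevels(x$y)))
  invisible(x)
}
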