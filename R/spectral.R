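#' Morlet continuous wavelet transform of one channel
#'
#' FFT-based convolution with complex Morlet wavelets of a fixed number of
#' cycles (default 7), so temporal resolution scales with frequency.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz (default 30 log-spaced points over
#'   1-50 Hz).
#' @param n_cycles Wavelet width in cycles.
#' @return Matrix of squared magnitudes (energy), frequencies x time.
#' @export
morlet_cwt <- function(x, fs, freqs = morlet_freqs(), n_cycles = 7) {
  n <- length(x)
  stopifnot(n >= 2, all(freqs > 0), all(freqs < fs / 2))
  Xf <- stats::fft(x)
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sd_t <- n_cycles / (2 * pi * f)
    half <- min(floor((n - 1) / 2), ceiling(4 * sd_t * fs))
    t <- (-half:half) / fs
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))            # unit-energy normalization
    wf <- numeric(n)
    wf[1:(half + 1)] <- Re(w[(half + 1):(2 * half + 1)])
    wi <- numeric(n)
    wi[1:(half + 1)] <- Im(w[(half + 1):(2 * half + 1)])
    if (half > 0) {
      wf[(n - half + 1):n] <- Re(w[1:half])
      wi[(n - half + 1):n] <- Im(w[1:half])
    }
    Wf <- stats::fft(wf + 1i * wi)
    conv <- stats::fft(Xf * Conj(Wf), inverse = TRUE) / n
    out[i, ] <- Mod(conv)^2
  }
  out
}

#' Default wavelet frequency axis: 30 log-spaced points over 1-50 Hz
#' @export
morlet_freqs <- function(n = 30, lo = 1, hi = 50) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Wavelet time-frequency map of a segment
#'
#' Continuous Morlet wavelet energy, averaged within non-overlapping windows
#' (default 5 s) and, optionally, across channels.
#'
#' @param seg A `session_segment` at least one window long.
#' @param window_s Non-overlapping averaging window in seconds (default 5).
#' @param freqs,n_cycles Passed to [morlet_cwt()].
#' @param aggregate `"channel-mean"` (default) returns a frequencies x
#'   windows matrix averaged over channels; `"per-channel"` returns a
#'   3-D array frequencies x windows x channels.
#' @return A `tf_map`: list with `energy`, `freqs`, `window_s`, `aggregate`.
#' @export
tf_wavelet <- function(seg, window_s = 5, freqs = morlet_freqs(),
                       n_cycles = 7,
                       aggregate = c("channel-mean", "per-channel")) {
  stopifnot(inherits(seg, "session_segment"))
  aggregate <- match.arg(aggregate)
  n_win <- round(window_s * seg$fs)
  starts <- window_starts(ncol(seg$samples), n_win)
  if (!length(starts))
    stop("segment shorter than one ", window_s, "-s window")
  nch <- nrow(seg$samples)
  per <- array(0, c(length(freqs), length(starts), nch))
  for (c in seq_len(nch)) {
    E <- morlet_cwt(seg$samples[c, ], seg$fs, freqs, n_cycles)
    for (w in seq_along(starts))
      per[, w, c] <- rowMeans(E[, starts[w]:(starts[w] + n_win - 1L),
                                drop = FALSE])
  }
  energy <- if (aggregate == "channel-mean") apply(per, c(1, 2), mean) else per
  structure(list(energy = energy, freqs = freqs, window_s = window_s,
                 aggregate = aggregate, channels = seg$channel_names),
            class = "tf_map")
}

#' Baseline-subtracted differential entropy topography
#'
#' Mean DE per channel and band over the segment windows, minus the mean DE
#' of the pre-stimulus baseline windows; with several tensors (e.g. across
#' sessions or subjects) the subtracted maps are averaged.
#'
#' @param de A `feature_tensor` of kind `"DE"` (channel units), or a list of
#'   them.
#' @param baseline_de Matching baseline DE tensor(s) (e.g.
#'   `de_features(seg, on = "baseline")`).
#' @param m Montage supplying 2-D positions.
#' @return A `topo_values`: list with `values` (channels x bands matrix, in
#'   nats), `positions`, `bands`.
#' @export
topo_de <- function(de, baseline_de, m = standard_montage()) {
  if (inherits(de, "feature_tensor")) de <- list(de)
  if (inherits(baseline_de, "feature_tensor")) baseline_de <- list(baseline_de)
  stopifnot(length(de) == length(baseline_de), length(de) >= 1)
  maps <- vector("list", length(de))
  for (i in seq_along(de)) {
    a <- de[[i]]; b <- baseline_de[[i]]
    if (!identical(a$units, b$units) || !identical(a$bands, b$bands))
      stop("channel/band axes of DE and baseline tensors do not match")
    maps[[i]] <- apply(a$values, c(2, 3), mean) - apply(b$values, c(2, 3), mean)
  }
  vals <- Reduce(`+`, maps) / length(maps)
  pos <- montage_positions(m, de[[1]]$units)
  structure(list(values = vals, positions = pos, bands = de[[1]]$bands),
            class = "topo_values")
}

#' Interpolate topographic values onto a head-model grid
#'
#' Gaussian radial-basis interpolation of per-channel values on the unit-disc
#' head model; values at the electrode sites are reproduced exactly, points
#' outside the disc (with margin for below-ring electrodes) are NA.
#'
#' @param tv A `topo_values` from [topo_de()].
#' @param band Band name to interpolate.
#' @param grid_n Grid resolution per axis (default 67).
#' @param bw Kernel bandwidth; defaults to the median inter-electrode
#'   distance.
#' @return List with `x`, `y` grid axes and `z` (grid_n x grid_n matrix).
#' @export
interpolate_scalp <- function(tv, band = tv$bands[1], grid_n = 67, bw = NULL) {
  stopifnot(inherits(tv, "topo_values"))
  b <- match(band, tv$bands)
  if (is.na(b)) stop("unknown band '", band, "'")
  v <- tv$values[, b]
  px <- tv$positions$x; py <- tv$positions$y
  n <- length(v)
  if (n < 4) stop("need at least 4 positioned channels")
  D <- as.matrix(stats::dist(cbind(px, py)))
  if (is.null(bw)) bw <- stats::median(D[upper.tri(D)])
  # Gaussian RBF augmented with a constant term, so flat maps are exact
  K <- exp(-(D / bw)^2)
  A <- rbind(cbind(K + diag(1e-8, n), 1), c(rep(1, n), 0))
  sol <- solve(A, c(v, 0))
  a <- sol[seq_len(n)]; c0 <- sol[n + 1]
  gx <- seq(-1.2, 1.2, length.out = grid_n)
  gy <- gx
  z <- matrix(NA_real_, grid_n, grid_n)
  r_max <- max(sqrt(px^2 + py^2)) * 1.02 + 1e-9
  for (i in seq_len(grid_n))
    for (j in seq_len(grid_n)) {
      if (gx[i]^2 + gy[j]^2 > r_max^2) next
      kk <- exp(-((gx[i] - px)^2 + (gy[j] - py)^2) / bw^2)
      z[i, j] <- sum(kk * a) + c0
    }
  list(x = gx, y = gy, z = z)
}
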