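#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is split into overlapping
#' segments of length L, each segment is windowed, its periodogram
#' `|FFT(x w)|^2 / (fs * sum(w^2))` computed, and the M periodograms are
#' averaged. One-sided density scaling (interior bins doubled), so that the
#' integral of the PSD over 0..fs/2 approximates the signal variance.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate, Hz.
#' @param segment_length segment length L in samples (<= length(x)).
#' @param overlap_fraction fraction of L shared by consecutive segments,
#'   in [0, 1).
#' @param window window name: "hamming", "hann" or "rect".
#' @param detrend subtract the per-segment mean before windowing.
#' @return list of class `psd_estimate`: `freq` (Hz, 0..fs/2), `power`
#'   (density, input-units^2/Hz), plus `segment_length`, `overlap_fraction`,
#'   `window`, `n_segments`, `fs` and the window normalization `u`
#'   (= sum(w^2)/L).
#' @examples
#' t <- seq(0, 8, by = 1/128)
#' p <- welch_psd(sin(2 * pi * 10 * t), fs = 128, segment_length = 256)
#' p$freq[which.max(p$power)]  # ~10 Hz
#' @export
welch_psd <- function(x, fs, segment_length = 256, overlap_fraction = 0.5,
                      window = c("hamming", "hann", "rect"), detrend = TRUE) {
  window <- match.arg(window)
  n <- length(x)
  L <- as.integer(segment_length)
  if (L < 2) stop("segment_length must be >= 2")
  if (L > n)
    stop("segment_length (", L, ") exceeds the signal length (", n, ")")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, L - 1) / (L - 1)),
    hann    = 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1))),
    rect    = rep(1, L)
  )
  u <- sum(w^2) / L                       # window normalization factor
  step <- max(1L, L - as.integer(round(overlap_fraction * L)))
  starts <- seq(1L, n - L + 1L, by = step)
  m <- length(starts)
  nfreq <- L %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend) seg <- seg - mean(seg)
    spec <- abs(stats::fft(seg * w))^2 / (fs * L * u)
    half <- spec[seq_len(nfreq)]
    # one-sided: double every bin except DC and (for even L) Nyquist
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (L %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + half * dbl
  }
  structure(
    list(freq = seq(0, nfreq - 1) * fs / L, power = acc / m,
         segment_length = L, overlap_fraction = overlap_fraction,
         window = window, n_segments = m, u = u, fs = fs),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate: %d bins 0-%g Hz, L=%d, %d segment(s), %s window>\n",
    length(x$freq), max(x$freq), x$segment_length, x$n_segments, x$window))
  invisible(x)
}

#' Integrated band power from a PSD estimate
#'
#' Trapezoidal integral of the spectral density over `[low, high]`, with
#' linear interpolation of the density at the band edges.
#'
#' @param psd a `psd_estimate` from [welch_psd()].
#' @param low,high band edges in Hz; must lie within the PSD frequency grid.
#' @return band power in input-units^2.
#' @export
band_power <- function(psd, low, high) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (low >= high) stop("need low < high")
  if (low < min(psd$freq) || high > max(psd$freq))
    stop("band [", low, ", ", high, "] Hz extends outside the PSD grid [",
         min(psd$freq), ", ", max(psd$freq), "] Hz")
  inside <- psd$freq > low & psd$freq < high
  f <- c(low, psd$freq[inside], high)
  p <- c(stats::approx(psd$freq, psd$power, xout = low)$y,
         psd$power[inside],
         stats::approx(psd$freq, psd$power, xout = high)$y)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}
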