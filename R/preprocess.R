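# forward-backward IIR filtering with odd-reflection end padding, so that
# startup transients decay inside the (discarded) pad rather than in the
# data. padlen is chosen from the slowest filter dynamics by the caller.
zero_phase_filter <- function(flt, x, padlen) {
  n <- length(x)
  padlen <- min(n - 1, max(9, round(padlen)))
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- signal::filtfilt(flt, ext)
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Mirrors the acquisition chain's 4th-order Butterworth bandpass
#' (24 dB/octave) as a software filter. Applied forward-backward
#' (zero-phase), so epoch-aligned features suffer no group delay; the
#' effective magnitude response is the squared single-pass response.
#'
#' @param rec a [recording()].
#' @param low,high passband corner frequencies, Hz (0 < low < high < fs/2).
#' @param order filter order of the underlying Butterworth design.
#' @return filtered [recording()] of identical shape and rate.
#' @examples
#' rec <- generate_eeg(eeg_sim_spec(n_channels = 1, duration = 4, seed = 1))
#' filtered <- bandpass_filter(rec, 4, 45)
#' @export
bandpass_filter <- function(rec, low = 4, high = 45, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop("high cutoff ", high, " Hz is at or above the Nyquist frequency (",
         nyq, " Hz)")
  if (order < 1) stop("order must be >= 1")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  padlen <- 3 * rec$fs / low          # ~3 time constants of the slowest pole
  out <- rec
  out$samples <- t(apply(rec$samples, 1,
                         function(x) zero_phase_filter(bf, x, padlen)))
  dimnames(out$samples) <- dimnames(rec$samples)
  out
}

#' Zero-phase IIR notch filter
#'
#' Removes narrowband power-line interference (default 50 Hz) with a
#' second-order IIR notch of quality factor Q, applied forward-backward.
#'
#' @param rec a [recording()].
#' @param freq notch center frequency, Hz (< fs/2).
#' @param q quality factor freq/bandwidth; higher is narrower.
#' @return filtered [recording()] of identical shape and rate.
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (freq >= nyq)
    stop("notch frequency ", freq, " Hz is at or above the Nyquist ",
         "frequency (", nyq, " Hz)")
  # standard RBJ biquad notch
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  padlen <- 3 * rec$fs / (freq / q)   # notch bandwidth sets the decay
  out <- rec
  out$samples <- t(apply(rec$samples, 1,
                         function(x) zero_phase_filter(flt, x, padlen)))
  dimnames(out$samples) <- dimnames(rec$samples)
  out
}

#' Default conditioning chain for one modality
#'
#' EEG: 4-45 Hz 4th-order Butterworth bandpass then a 50 Hz notch.
#' ECG (HRV path): 0.5-40 Hz bandpass then a 50 Hz notch. QRS detection in
#' [pan_tompkins()] applies its own internal 5-15 Hz stage on top.
#'
#' @param rec a [recording()].
#' @return conditioned [recording()].
#' @export
preprocess_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$modality == "eeg") {
    rec <- bandpass_filter(rec, 4, 45)
  } else {
    rec <- bandpass_filter(rec, 0.5, 40)
  }
  if (rec$fs / 2 > 50) rec <- notch_filter(rec, 50) else rec
}
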