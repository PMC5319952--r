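#' Canonical EEG frequency bands
#'
#' The four bands analysed throughout the package: theta 4-8 Hz, alpha
#' 8-13 Hz, beta 13-30 Hz, gamma 30-45 Hz. Band intervals are half-open
#' `[low, high)` except gamma, which closes at 45 Hz.
#'
#' @return data.frame with columns `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("theta", "alpha", "beta", "gamma"),
    low  = c(4, 8, 13, 30),
    high = c(8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic EEG recording
#'
#' Describes an EEG signal as a sum of band-limited oscillations (one per
#' canonical band, each with a prescribed RMS amplitude) plus 1/f^exponent
#' background noise. Band-limited content is realised as bandpass-filtered
#' white noise rescaled to the requested RMS, not a pure sinusoid, so that
#' spectral features behave as they do on real broadband EEG.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz. Must exceed twice the upper edge of the
#'   highest band with nonzero amplitude.
#' @param duration recording length, seconds.
#' @param band_amplitudes named numeric vector of per-band RMS amplitudes in
#'   microvolts; names among theta/alpha/beta/gamma.
#' @param noise_exponent slope of the 1/f background (power ~ 1/f^exponent).
#' @param noise_amplitude RMS amplitude of the background noise, microvolts.
#' @param seed integer seed; identical spec + seed reproduce the recording
#'   bit for bit.
#' @param channel_labels optional channel names (default ch1..chN).
#' @return list of class `eeg_sim_spec`.
#' @seealso [generate_eeg()]
#' @export
eeg_sim_spec <- function(n_channels = 8, fs = 128, duration = 60,
                         band_amplitudes = c(theta = 6, alpha = 10,
                                             beta = 5, gamma = 3),
                         noise_exponent = 1, noise_amplitude = 5,
                         seed = 1L, channel_labels = NULL) {
  bands <- eeg_bands()
  amp <- rep(0, nrow(bands)); names(amp) <- bands$band
  if (length(band_amplitudes)) {
    if (is.null(names(band_amplitudes)) ||
        !all(names(band_amplitudes) %in% bands$band))
      stop("band_amplitudes must be named with bands among: ",
           paste(bands$band, collapse = ", "))
    amp[names(band_amplitudes)] <- band_amplitudes
  }
  if (any(amp < 0) || noise_amplitude < 0)
    stop("amplitudes must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  active <- bands[amp[bands$band] > 0, , drop = FALSE]
  if (nrow(active) && fs <= 2 * max(active$high))
    stop("fs = ", fs, " Hz violates the Nyquist criterion for the ",
         active$band[which.max(active$high)], " band (upper edge ",
         max(active$high), " Hz requires fs > ", 2 * max(active$high), " Hz)")
  structure(
    list(n_channels = n_channels, fs = fs, duration = duration,
         band_amplitudes = amp, noise_exponent = noise_exponent,
         noise_amplitude = noise_amplitude, seed = as.integer(seed),
         channel_labels = channel_labels),
    class = "eeg_sim_spec"
  )
}

# white noise with spectrum shaped to 1/f^exponent, rescaled to target RMS
pink_noise <- function(n, exponent, rms_target) {
  if (rms_target == 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f)            # two-sided frequency magnitude
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms_target / sqrt(mean(x^2))
}

# band-limited oscillation: white noise -> 4th-order Butterworth bandpass ->
# rescale to requested RMS; random phase comes with the noise realisation
band_oscillation <- function(n, fs, low, high, rms_target) {
  if (rms_target == 0) return(numeric(n))
  w <- stats::rnorm(n)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  x * rms_target / sqrt(mean(x^2))
}

#' Generate a synthetic EEG recording
#'
#' Each channel is an independent realisation of
#' sum over bands of (band-limited oscillation at the requested RMS) plus
#' 1/f^exponent background noise.
#'
#' @param spec an [eeg_sim_spec()].
#' @return a [recording()] with modality "eeg".
#' @examples
#' spec <- eeg_sim_spec(n_channels = 2, duration = 10, seed = 42)
#' rec <- generate_eeg(spec)
#' @export
generate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  bands <- eeg_bands()
  samples <- matrix(0, nrow = spec$n_channels, ncol = n)
  for (ch in seq_len(spec$n_channels)) {
    x <- numeric(n)
    for (k in seq_len(nrow(bands))) {
      a <- spec$band_amplitudes[[bands$band[k]]]
      if (a > 0)
        x <- x + band_oscillation(n, spec$fs, bands$low[k], bands$high[k], a)
    }
    if (spec$noise_amplitude > 0)
      x <- x + pink_noise(n, spec$noise_exponent, spec$noise_amplitude)
    samples[ch, ] <- x
  }
  recording(samples, fs = spec$fs,
            channel_labels = spec$channel_labels %||%
              paste0("ch", seq_len(spec$n_channels)),
            modality = "eeg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
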