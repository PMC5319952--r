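#' Specification for a synthetic RR-interval series
#'
#' Describes a beat-to-beat interval (tachogram) model: a mean RR interval
#' modulated by one low-frequency (LF, 0.04-0.15 Hz) and one high-frequency
#' (HF, 0.15-0.4 Hz) sinusoid — standing in for sympathetic/baroreflex and
#' respiratory (vagal) modulation respectively — plus white beat-to-beat
#' jitter.
#'
#' @param mean_rr mean RR interval, ms.
#' @param n_beats number of intervals to generate (>= 2).
#' @param lf_mod_amplitude,lf_mod_freq LF modulation: amplitude in ms,
#'   frequency in Hz within [0.04, 0.15].
#' @param hf_mod_amplitude,hf_mod_freq HF modulation: amplitude in ms,
#'   frequency in Hz within [0.15, 0.4].
#' @param jitter_sd standard deviation of additive white jitter, ms.
#' @param seed integer seed.
#' @return list of class `hrv_sim_spec`.
#' @seealso [generate_rr_series()], [generate_ecg()]
#' @export
hrv_sim_spec <- function(mean_rr = 850, n_beats = 300,
                         lf_mod_amplitude = 40, lf_mod_freq = 0.1,
                         hf_mod_amplitude = 30, hf_mod_freq = 0.25,
                         jitter_sd = 15, seed = 1L) {
  if (mean_rr <= 0) stop("mean_rr must be > 0")
  if (n_beats < 2) stop("n_beats must be >= 2")
  if (lf_mod_freq < 0.04 || lf_mod_freq > 0.15)
    stop("lf_mod_freq must lie in [0.04, 0.15] Hz")
  if (hf_mod_freq < 0.15 || hf_mod_freq > 0.4)
    stop("hf_mod_freq must lie in [0.15, 0.4] Hz")
  if (lf_mod_amplitude < 0 || hf_mod_amplitude < 0 || jitter_sd < 0)
    stop("amplitudes and jitter_sd must be >= 0")
  if (lf_mod_amplitude + hf_mod_amplitude >= mean_rr)
    stop("modulation amplitudes must sum to less than mean_rr ",
         "(would admit nonpositive intervals)")
  structure(
    list(mean_rr = mean_rr, n_beats = as.integer(n_beats),
         lf_mod_amplitude = lf_mod_amplitude, lf_mod_freq = lf_mod_freq,
         hf_mod_amplitude = hf_mod_amplitude, hf_mod_freq = hf_mod_freq,
         jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "hrv_sim_spec"
  )
}

#' Ordered RR-interval series
#'
#' @param intervals inter-beat intervals in ms, all > 0.
#' @return list of class `rr_series` with `intervals` (ms), `beat_times`
#'   (cumulative ms, first beat at 0) and `physiological` (TRUE unless any
#'   interval falls outside 300-2000 ms).
#' @export
rr_series <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (!length(intervals)) stop("empty RR series")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be finite and > 0")
  structure(
    list(intervals = intervals,
         beat_times = c(0, cumsum(intervals)),
         physiological = all(intervals >= 300 & intervals <= 2000)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series: %d intervals, mean %.1f ms, span %.1f s%s>\n",
              length(x$intervals), mean(x$intervals),
              max(x$beat_times) / 1000,
              if (x$physiological) "" else ", OUTSIDE 300-2000 ms"))
  invisible(x)
}

#' Generate an RR-interval series from a tachogram model
#'
#' Beat i at cumulative time t_i receives
#' `RR_i = mean_rr + A_lf sin(2 pi f_lf t_i) + A_hf sin(2 pi f_hf t_i) +
#' jitter_i`, with t_i the time of the beat opening the interval.
#'
#' @param spec an [hrv_sim_spec()].
#' @return an [rr_series()].
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "hrv_sim_spec"))
  set.seed(spec$seed)
  jitter <- if (spec$jitter_sd > 0)
    stats::rnorm(spec$n_beats, sd = spec$jitter_sd) else numeric(spec$n_beats)
  rr <- numeric(spec$n_beats)
  t_i <- 0  # seconds, time of the beat that opens interval i
  for (i in seq_len(spec$n_beats)) {
    rr[i] <- spec$mean_rr +
      spec$lf_mod_amplitude * sin(2 * pi * spec$lf_mod_freq * t_i) +
      spec$hf_mod_amplitude * sin(2 * pi * spec$hf_mod_freq * t_i) +
      jitter[i]
    if (rr[i] <= 0)
      stop("generated a nonpositive RR interval; reduce jitter_sd or ",
           "modulation amplitudes")
    t_i <- t_i + rr[i] / 1000
  }
  rr_series(rr)
}

#' ECG morphology template
#'
#' Per-beat waveform as a sum of Gaussian bumps: P wave, Q/R/S complex and T
#' wave. Defaults are typical lead-II values: dominant positive R of 1 mV
#' with a QRS width of 80 ms, flanked by small negative Q and S deflections,
#' P at 0.15 mV and T at 0.3 mV.
#'
#' @param r_amplitude R-peak amplitude, mV.
#' @param qrs_width total QRS duration, ms.
#' @param p_amplitude,t_amplitude P- and T-wave amplitudes, mV.
#' @return list of class `ecg_morphology`: one row per wave with amplitude
#'   (mV), center offset from the R peak (ms) and Gaussian sigma (ms).
#' @export
ecg_morphology <- function(r_amplitude = 1.0, qrs_width = 80,
                           p_amplitude = 0.15, t_amplitude = 0.3) {
  stopifnot(r_amplitude > 0, qrs_width > 0)
  structure(
    data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      amp    = c(p_amplitude, -0.15 * r_amplitude, r_amplitude,
                 -0.25 * r_amplitude, t_amplitude),
      center = c(-180, -qrs_width / 3, 0, qrs_width / 3, 250),
      sigma  = c(25, qrs_width / 10, qrs_width / 8, qrs_width / 10, 45),
      stringsAsFactors = FALSE
    ),
    class = c("ecg_morphology", "data.frame")
  )
}

# full extent of the template left/right of the R peak, ms (3 sigma)
morphology_extent <- function(m) {
  c(left = -min(m$center - 3 * m$sigma), right = max(m$center + 3 * m$sigma))
}

#' Synthesise an ECG waveform from an RR series
#'
#' Places one morphology template at each cumulative beat time. The true
#' R-peak sample indices are returned as ground truth for detector
#' validation.
#'
#' @param rr an [rr_series()].
#' @param fs sampling rate, Hz (>= 250).
#' @param morphology an [ecg_morphology()].
#' @param metadata metadata list passed to the [recording()].
#' @return a [recording()] (modality "ecg", single channel "II") with the
#'   1-based ground-truth R-peak indices in `metadata$r_peaks`. An RR series
#'   of n intervals yields n + 1 peaks.
#' @export
generate_ecg <- function(rr, fs = 500, morphology = ecg_morphology(),
                         metadata = list()) {
  stopifnot(inherits(rr, "rr_series"), inherits(morphology, "ecg_morphology"))
  if (fs < 250) stop("fs must be >= 250 Hz for adequate QRS sampling")
  ext <- morphology_extent(morphology)
  if (sum(ext) >= min(rr$intervals))
    stop("morphology template (", round(sum(ext)), " ms) is wider than the ",
         "shortest RR interval (", round(min(rr$intervals)),
         " ms): beats would overlap")
  # R-peak sample positions; quantized beat times, as an acquisition would
  # see. A lead-in margin keeps the first beat's template fully in-record.
  lead_in <- round(ext[["left"]] * fs / 1000) + 1L
  peak_idx <- round(rr$beat_times * fs / 1000) + lead_in
  n <- max(peak_idx) + round(ext[["right"]] * fs / 1000) + 1L
  x <- numeric(n)
  half <- ceiling((max(ext) + 50) * fs / 1000)
  for (p in peak_idx) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    t_ms <- (seq(lo, hi) - p) * 1000 / fs   # ms relative to the R peak
    for (w in seq_len(nrow(morphology)))
      x[lo:hi] <- x[lo:hi] + morphology$amp[w] *
        exp(-0.5 * ((t_ms - morphology$center[w]) / morphology$sigma[w])^2)
  }
  metadata$r_peaks <- peak_idx
  recording(matrix(x, nrow = 1), fs = fs, channel_labels = "II",
            modality = "ecg", metadata = metadata)
}
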