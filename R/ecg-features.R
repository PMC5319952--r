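#' Pan-Tompkins QRS detection
#'
#' The classic stage chain: 5-15 Hz bandpass, five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual-threshold
#' peak picking on the integrated signal with running signal/noise level
#' estimates, a 200 ms refractory period, and a search-back at 1.66x the
#' running RR average using the lower threshold. Thresholds are initialized
#' from the first two seconds of the integrated signal. Detected peaks are
#' finally refined to the local maximum of the bandpassed waveform within
#' +/- 50 ms, so the reported indices land on the R wave itself.
#'
#' All thresholds are relative to the signal's own running levels, so
#' detection is invariant to positive amplitude scaling.
#'
#' @param x single-channel ECG samples (or an ECG [recording()], whose
#'   first channel is used).
#' @param fs sampling rate, Hz (>= 200).
#' @return list of class `r_peak_series`: `peaks` (1-based sample indices,
#'   strictly increasing), `fs`. Empty (with a warning) when nothing
#'   crosses threshold.
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Trans Biomed Eng 32(3):230-236.
#' @export
pan_tompkins <- function(x, fs = NULL) {
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- as.numeric(x$samples[1, ])
  }
  if (is.null(fs)) stop("fs required when x is a plain vector")
  if (fs < 200) stop("fs must be >= 200 Hz for QRS detection")
  if (any(!is.finite(x))) stop("non-finite samples in ECG input")
  n <- length(x)
  if (n < 5 * fs) stop("need at least 5 s of ECG")
  empty <- structure(list(peaks = integer(0), fs = fs),
                     class = "r_peak_series")
  if (all(x == x[1])) {
    warning("flat signal: no QRS complexes found")
    return(empty)
  }

  ## stage 1: 5-15 Hz bandpass (zero phase)
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- zero_phase_filter(bf, x, padlen = 3 * fs / 5)
  ## stage 2: derivative (five-point, Pan-Tompkins kernel)
  dk <- c(1, 2, 0, -2, -1) * fs / 8
  xd <- stats::filter(xf, rev(dk), sides = 2)
  xd[is.na(xd)] <- 0
  ## stage 3: squaring
  xs <- as.numeric(xd)^2
  ## stage 4: moving-window integration, 150 ms
  win <- max(1L, round(0.150 * fs))
  xi <- as.numeric(stats::filter(xs, rep(1 / win, win), sides = 2))
  xi[is.na(xi)] <- 0

  ## candidate peaks of the integrated signal (local maxima, >=200 ms apart)
  refractory <- round(0.200 * fs)
  cand <- which(diff(sign(diff(xi))) < 0) + 1L
  if (!length(cand)) {
    warning("no peaks found in integrated signal")
    return(empty)
  }

  ## adaptive thresholding
  init <- xi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.5          # running signal level
  npki <- mean(init) * 0.5         # running noise level
  thr1 <- npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_avg <- NA_real_
  last_qrs <- -Inf
  i <- 1
  while (i <= length(cand)) {
    p <- cand[i]
    v <- xi[p]
    if (p - last_qrs < refractory) { i <- i + 1; next }
    if (v > thr1) {
      qrs <- c(qrs, p)
      if (length(qrs) >= 2) {
        rr_new <- p - last_qrs
        rr_avg <- if (is.na(rr_avg)) rr_new else 0.875 * rr_avg + 0.125 * rr_new
      }
      last_qrs <- p
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
      ## search-back: if no QRS within 1.66x the running RR, take the
      ## largest missed candidate above the lower threshold thr1/2
      if (!is.na(rr_avg) && p - last_qrs > 1.66 * rr_avg) {
        miss <- cand[cand > last_qrs + refractory & cand <= p]
        miss <- miss[xi[miss] > thr1 / 2]
        if (length(miss)) {
          pb <- miss[which.max(xi[miss])]
          qrs <- sort(c(qrs, pb))
          rr_avg <- 0.875 * rr_avg + 0.125 * (pb - last_qrs)
          last_qrs <- max(qrs)
          spki <- 0.25 * xi[pb] + 0.75 * spki
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1
  }
  if (!length(qrs)) {
    warning("no QRS complexes found above threshold")
    return(empty)
  }

  ## refine in two steps: the zero-phase integrator peaks on a broad
  ## plateau anywhere within its 150 ms window, so first locate the QRS on
  ## the bandpassed signal within that window, then polish to the local
  ## waveform maximum within +/- 50 ms on the raw trace
  half <- round(0.050 * fs)
  peaks <- vapply(qrs, function(p) {
    lo <- max(1, p - win); hi <- min(n, p + win)
    c0 <- lo + which.max(xf[lo:hi]) - 1
    lo <- max(1, c0 - half); hi <- min(n, c0 + half)
    as.integer(lo + which.max(x[lo:hi]) - 1)
  }, integer(1))
  peaks <- sort(unique(peaks))
  ## enforce the refractory period after refinement, keeping larger waves
  keep <- rep(TRUE, length(peaks))
  j <- 1
  for (k in seq_along(peaks)[-1]) {
    if (peaks[k] - peaks[j] < refractory) {
      if (x[peaks[k]] > x[peaks[j]]) { keep[j] <- FALSE; j <- k }
      else keep[k] <- FALSE
    } else j <- k
  }
  structure(list(peaks = peaks[keep], fs = fs), class = "r_peak_series")
}

#' @export
print.r_peak_series <- function(x, ...) {
  cat(sprintf("<r_peak_series: %d peaks @ %g Hz>\n", length(x$peaks), x$fs))
  invisible(x)
}

#' RR intervals from detected R peaks
#'
#' `interval_i = (x_{i+1} - x_i) / fs`, reported in ms.
#'
#' @param peaks an `r_peak_series` from [pan_tompkins()] (or a numeric
#'   vector of sample indices, with `fs` supplied).
#' @param fs sampling rate when `peaks` is a plain vector.
#' @return an [rr_series()] with n - 1 intervals for n peaks.
#' @export
rr_intervals <- function(peaks, fs = NULL) {
  if (inherits(peaks, "r_peak_series")) {
    fs <- peaks$fs
    peaks <- peaks$peaks
  }
  if (is.null(fs)) stop("fs required when peaks is a plain vector")
  if (length(peaks) < 2) stop("need at least 2 peaks to form RR intervals")
  if (any(diff(peaks) <= 0)) stop("peak indices must be strictly increasing")
  rr_series(diff(peaks) / fs * 1000)
}

#' Time-domain HRV features
#'
#' Mean RR; NN50 = number of successive-interval pairs differing by more
#' than 50 ms; pNN50 = 100 * NN50 / (number of pairs).
#'
#' @param rr an [rr_series()].
#' @return list with `rr_mean` (ms), `nn50` (count), `pnn50` (%). With a
#'   single interval, `nn50`/`pnn50` are NA and `undefined = TRUE`.
#' @export
time_domain_hrv <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  iv <- rr$intervals
  if (length(iv) < 2)
    return(list(rr_mean = mean(iv), nn50 = NA_integer_, pnn50 = NA_real_,
                undefined = TRUE))
  d <- abs(diff(iv))
  nn50 <- sum(d > 50)
  list(rr_mean = mean(iv), nn50 = nn50, pnn50 = 100 * nn50 / length(d),
       undefined = FALSE)
}

#' Frequency-domain HRV features
#'
#' The irregularly sampled tachogram (RR vs beat time) is interpolated to a
#' uniform grid by cubic spline, mean-detrended, and its Welch PSD
#' integrated over LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz). The
#' sympathovagal balance index is SVI = LF/HF.
#'
#' @param rr an [rr_series()]; total duration must be >= 60 s (a warning is
#'   issued under 250 s, where the LF band is poorly resolved).
#' @param resample_rate uniform tachogram rate, Hz (default 4).
#' @param segment_seconds Welch segment length in seconds (default 120,
#'   shortened to the record when necessary).
#' @param overlap_fraction Welch overlap (default 0.5).
#' @return list with `lf_power`, `hf_power` (ms^2), `svi` (NA with
#'   `svi_undefined = TRUE` when HF power is numerically zero).
#' @export
frequency_domain_hrv <- function(rr, resample_rate = 4,
                                 segment_seconds = 120,
                                 overlap_fraction = 0.5) {
  stopifnot(inherits(rr, "rr_series"))
  dur <- max(rr$beat_times) / 1000
  if (dur < 60)
    stop("tachogram spans only ", round(dur, 1),
         " s; >= 60 s required to resolve the LF band")
  if (dur < 250)
    warning("tachogram spans ", round(dur), " s; LF estimates are unstable ",
            "below 250 s")
  t_beat <- rr$beat_times[-1] / 1000     # interval i closes at beat i+1
  grid <- seq(min(t_beat), max(t_beat), by = 1 / resample_rate)
  tach <- stats::spline(t_beat, rr$intervals, xout = grid, method = "fmm")$y
  tach <- tach - mean(tach)
  seg <- min(round(segment_seconds * resample_rate), length(tach))
  psd <- welch_psd(tach, fs = resample_rate, segment_length = seg,
                   overlap_fraction = overlap_fraction, window = "hamming")
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  floor_p <- .Machine$double.eps * sum(psd$power)
  if (hf <= floor_p)
    list(lf_power = lf, hf_power = hf, svi = NA_real_, svi_undefined = TRUE)
  else
    list(lf_power = lf, hf_power = hf, svi = lf / hf, svi_undefined = FALSE)
}

#' Full HRV pipeline for one ECG recording
#'
#' [pan_tompkins()] detection, [rr_intervals()], then time- and
#' frequency-domain features, composed into one feature row.
#'
#' @param rec an ECG [recording()].
#' @param ... passed to [frequency_domain_hrv()].
#' @return data.frame of class `hrv_features` with one row: any
#'   subject/group/session/condition metadata, then `rr_mean`, `nn50`,
#'   `pnn50`, `lf_power`, `hf_power`, `svi`, `n_beats`.
#' @export
hrv_pipeline <- function(rec, ...) {
  stopifnot(inherits(rec, "recording"))
  if (rec$modality != "ecg") stop("hrv_pipeline expects an ECG recording")
  pk <- pan_tompkins(rec)
  rr <- rr_intervals(pk)
  td <- time_domain_hrv(rr)
  fd <- frequency_domain_hrv(rr, ...)
  keys <- rec$metadata[intersect(c("subject", "group", "session", "condition"),
                                 names(rec$metadata))]
  out <- data.frame(
    c(keys, list(rr_mean = td$rr_mean, nn50 = td$nn50, pnn50 = td$pnn50,
                 lf_power = fd$lf_power, hf_power = fd$hf_power,
                 svi = fd$svi, n_beats = length(pk$peaks))),
    stringsAsFactors = FALSE)
  class(out) <- c("hrv_features", "data.frame")
  out
}
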