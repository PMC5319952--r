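#' Root mean square of a signal
#'
#' `sqrt(mean(x^2))`. Low RMS in an EEG epoch indicates desynchronized
#' activity.
#'
#' @param x numeric vector, length >= 1.
#' @return nonnegative scalar.
#' @export
signal_rms <- function(x) {
  if (!length(x)) stop("cannot take the RMS of an empty signal")
  if (any(!is.finite(x))) stop("non-finite samples in RMS input")
  sqrt(mean(x^2))
}

#' EEG engagement index
#'
#' `EI = beta / (alpha + theta)`, the PSD-ratio index of task engagement:
#' beta power rises and alpha is suppressed as workload increases, so EI
#' increases with engagement.
#'
#' @param p_theta,p_alpha,p_beta band powers (any common unit, >= 0).
#' @return unitless index.
#' @export
engagement_index <- function(p_theta, p_alpha, p_beta) {
  if (any(c(p_theta, p_alpha, p_beta) < 0))
    stop("band powers must be >= 0")
  if (p_alpha + p_theta <= 0)
    stop("engagement index undefined: alpha + theta power is zero ",
         "(dead or unfiltered channel?)")
  p_beta / (p_alpha + p_theta)
}

#' The eight frontal / fronto-central channels used for workload analysis
#' @return character vector of 10-20 labels.
#' @export
frontal_channels <- function() {
  c("AF3", "F7", "F3", "FC5", "FC6", "F4", "F8", "AF4")
}

#' Extract per-epoch EEG features from a recording
#'
#' Splits each requested channel into consecutive non-overlapping epochs and
#' computes, per channel x epoch: wavelet band energies (raw `e_*` and
#' normalized `pl_*`, via [dwt_band_energies()]), RMS, Welch band powers for
#' theta/alpha/beta/gamma (`p_*`, via [welch_psd()] + [band_power()]) and
#' the engagement index `ei`. All-zero (dead-channel) epochs yield a zero
#' row flagged `degenerate` rather than an error, so batch runs survive.
#'
#' @param rec an EEG [recording()].
#' @param channels channel labels to analyse; default the eight frontal /
#'   fronto-central ones when present, otherwise all channels.
#' @param epoch_length epoch duration, seconds (default 4).
#' @param segment_length,overlap_fraction,window Welch parameters
#'   (defaults: 256 samples, 50%, Hamming).
#' @return data.frame of class `eeg_feature_table`, one row per channel x
#'   epoch, carrying any subject/group/session/condition metadata of the
#'   recording as leading key columns.
#' @export
extract_features <- function(rec, channels = NULL, epoch_length = 4,
                             segment_length = 256, overlap_fraction = 0.5,
                             window = "hamming") {
  stopifnot(inherits(rec, "recording"))
  if (is.null(channels)) {
    channels <- intersect(frontal_channels(), rec$channel_labels)
    if (!length(channels)) channels <- rec$channel_labels
  }
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing))
    stop("channel(s) absent from recording: ", paste(missing, collapse = ", "))
  epoch_n <- round(epoch_length * rec$fs)
  n_epochs <- n_samples(rec) %/% epoch_n
  if (n_epochs < 1)
    stop("recording shorter than one epoch (", epoch_length, " s)")
  seg <- min(segment_length, epoch_n)
  bands <- eeg_bands()

  keys <- rec$metadata[intersect(c("subject", "group", "session", "condition"),
                                 names(rec$metadata))]
  rows <- vector("list", length(channels) * n_epochs)
  i <- 0
  for (ch in channels) {
    x <- channel_data(rec, ch)
    for (ep in seq_len(n_epochs)) {
      xe <- x[((ep - 1) * epoch_n + 1):(ep * epoch_n)]
      i <- i + 1
      if (all(xe == 0)) {
        rows[[i]] <- data.frame(
          c(keys, list(channel = ch, epoch = ep,
            e_theta = 0, e_alpha = 0, e_beta = 0, e_gamma = 0,
            pl_theta = 0, pl_alpha = 0, pl_beta = 0, pl_gamma = 0,
            rms = 0, p_theta = 0, p_alpha = 0, p_beta = 0, p_gamma = 0,
            ei = 0, degenerate = TRUE)),
          stringsAsFactors = FALSE)
        next
      }
      be <- dwt_band_energies(xe, fs = rec$fs)
      psd <- welch_psd(xe, fs = rec$fs, segment_length = seg,
                       overlap_fraction = overlap_fraction, window = window)
      bp <- stats::setNames(
        vapply(seq_len(nrow(bands)),
               function(k) band_power(psd, bands$low[k], bands$high[k]),
               numeric(1)),
        bands$band)
      rows[[i]] <- data.frame(
        c(keys, list(channel = ch, epoch = ep,
          e_theta = be$energy[["theta"]], e_alpha = be$energy[["alpha"]],
          e_beta = be$energy[["beta"]], e_gamma = be$energy[["gamma"]],
          pl_theta = be$pl[["theta"]], pl_alpha = be$pl[["alpha"]],
          pl_beta = be$pl[["beta"]], pl_gamma = be$pl[["gamma"]],
          rms = signal_rms(xe),
          p_theta = bp[["theta"]], p_alpha = bp[["alpha"]],
          p_beta = bp[["beta"]], p_gamma = bp[["gamma"]],
          ei = engagement_index(bp[["theta"]], bp[["alpha"]], bp[["beta"]]),
          degenerate = FALSE)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eeg_feature_table", "data.frame")
  out
}
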