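#' Multichannel biosignal recording
#'
#' Container for a uniformly sampled multichannel signal plus study metadata.
#' EEG samples are in microvolts, ECG in millivolts.
#'
#' @param samples numeric matrix, channels x time.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel (10-20
#'   electrode names for EEG, lead names for ECG).
#' @param modality "eeg" or "ecg".
#' @param metadata named list of study keys (subject, group, session,
#'   condition, ...). Free-form; carried through the pipeline unchanged.
#'
#' @return An object of class `recording`: a list with elements `samples`,
#'   `fs`, `channel_labels`, `modality`, `metadata`.
#' @examples
#' x <- matrix(rnorm(256), nrow = 2)
#' rec <- recording(x, fs = 128, channel_labels = c("AF3", "AF4"))
#' n_samples(rec)
#' @export
recording <- function(samples, fs, channel_labels = NULL,
                      modality = c("eeg", "ecg"), metadata = list()) {
  modality <- match.arg(modality)
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("'fs' must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("length(channel_labels) must equal the number of channels (rows)")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         modality = modality, metadata = metadata),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %s, %d channel(s) x %d samples @ %g Hz (%.1f s)>\n",
              x$modality, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname recording
#' @param rec a `recording`.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Extract one channel as a numeric vector
#' @param rec a `recording`.
#' @param channel channel label or index.
#' @return numeric vector of samples.
#' @export
channel_data <- function(rec, channel) {
  if (is.character(channel) && !channel %in% rec$channel_labels)
    stop("channel '", channel, "' not present; available: ",
         paste(rec$channel_labels, collapse = ", "))
  as.numeric(rec$samples[channel, ])
}

# deterministic polynomial string hash; used to derive per-cell child seeds
# so that cell-level reproducibility is independent of generation order.
# modulus < 2^26 keeps every intermediate product exact in double precision.
hash_seed <- function(..., master = 0L) {
  key <- paste(c(master, ...), collapse = "|")
  m <- 67108859  # prime below 2^26
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer(h)
}
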