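#' Write a recording to CSV
#'
#' Long-by-time wide-by-channel dialect: first column `time` in seconds,
#' one column per channel, values in the recording's physical unit.
#'
#' @param rec a [recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- data.frame(time = (seq_len(n_samples(rec)) - 1) / rec$fs,
                   t(rec$samples), check.names = FALSE)
  names(df) <- c("time", rec$channel_labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects the [write_recording_csv()] dialect. The sampling rate is
#' inferred from the time column, which must be uniform.
#'
#' @param path CSV file.
#' @param modality "eeg" or "ecg".
#' @param metadata metadata list attached to the recording.
#' @return a [recording()].
#' @export
read_recording_csv <- function(path, modality = "eeg", metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "time")
    stop("malformed recording CSV (", path,
         "): first column must be 'time'")
  if (nrow(df) < 2) stop("recording CSV has fewer than 2 samples: ", path)
  dt <- diff(df$time)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]) || dt[1] <= 0)
    stop("non-uniform sampling in ", path, " near row ",
         which(abs(dt - dt[1]) > 1e-6 * dt[1])[1] + 1)
  if (anyNA(df)) stop("missing samples in ", path)
  recording(t(as.matrix(df[, -1, drop = FALSE])), fs = 1 / dt[1],
            channel_labels = names(df)[-1], modality = modality,
            metadata = metadata)
}

# ---- minimal EDF (16-bit European Data Format) writer/reader -------------
# Continuous signals only, one data record holding the whole recording
# (fractional record durations are part of the format). Good for
# interchange of the pipeline's recordings; not a general clinical reader.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = -width, flag = "-")
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one data record spanning the full recording. Physical
#' scaling per channel is chosen from the data range, so the round trip is
#' exact to one 16-bit quantization step.
#'
#' @param rec a [recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$samples); n <- n_samples(rec)
  pmin_ <- apply(rec$samples, 1, min); pmax_ <- apply(rec$samples, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste("X X X", rec$modality), 80),
    edf_pad(paste("Startdate X X X", rec$modality), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad(toupper(rec$modality), 44),
    edf_pad(1, 8), edf_pad(format(n / rec$fs, digits = 8), 8),
    edf_pad(ns, 4))
  field <- function(vals, width)
    paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(rec$channel_labels, 16), field(rep("", ns), 80),
    field(rep(if (rec$modality == "eeg") "uV" else "mV", ns), 8),
    field(format(pmin_, digits = 8), 8), field(format(pmax_, digits = 8), 8),
    field(rep(dmin, ns), 8), field(rep(dmax, ns), 8),
    field(rep("", ns), 80), field(rep(n, ns), 8), field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((rec$samples[ch, ] - pmin_[ch]) /
                   (pmax_[ch] - pmin_[ch]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads continuous 16-bit EDF files (any number of data records, equal
#' samples-per-record across records).
#'
#' @param path EDF file.
#' @param modality "eeg" or "ecg".
#' @param metadata metadata list attached to the recording.
#' @return a [recording()].
#' @export
read_recording_edf <- function(path, modality = "eeg", metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8 + 80 + 80 + 8 + 8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path)
  sig_field <- function(width)
    vapply(seq_len(ns), function(i) rd(width), "")
  labels <- sig_field(16); sig_field(80); sig_field(8)
  pmin_ <- as.numeric(sig_field(8)); pmax_ <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)
  spr <- as.integer(sig_field(8))
  sig_field(32)
  if (length(unique(spr)) != 1)
    stop("EDF with differing per-signal rates is not supported: ", path)
  expected <- header_bytes + 2 * n_rec * sum(spr)
  if (file.size(path) < expected)
    stop("truncated EDF file ", path, ": expected ", expected,
         " bytes, found ", file.size(path))
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) for (ch in seq_len(ns)) {
    dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                   endian = "little")
    samples[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
      pmin_[ch] + (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch])
  }
  recording(samples, fs = spr[1] / rec_dur, channel_labels = labels,
            modality = modality, metadata = metadata)
}

#' Read a recording, dispatching on format
#'
#' @param path file path.
#' @param format "csv", "edf", or NULL to infer from the extension.
#' @param ... passed to the format reader.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = NULL, ...) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         csv = read_recording_csv(path, ...),
         edf = read_recording_edf(path, ...),
         stop("unsupported recording format '", format, "'"))
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one validated list; every default
#' matches the package's documented choices (4-45 Hz EEG bandpass, 50 Hz
#' notch, 4-s epochs, 256-sample Hamming Welch segments, 4 Hz tachogram,
#' 20/15/65 split).
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides for any config entry.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cogload_run_"), seed = 1L,
                            ...) {
  cfg <- utils::modifyList(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_control = 10, n_experimental = 15,
         effect_size = 0.2, subject_cv = 0.05,
         eeg_duration = 64, ecg_duration = 300,
         epoch_length = 4, eeg_variable = "ei",
         split_fractions = c(0.20, 0.15, 0.65),
         svm_cost = 1, nn_hidden = 10),
    list(...))
  stopifnot(cfg$epoch_length > 0, cfg$eeg_duration >= cfg$epoch_length,
            abs(sum(cfg$split_fractions) - 1) < 1e-9,
            cfg$effect_size >= 0, cfg$ecg_duration >= 60)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg)
  hash_seed(paste(deparse(unclass(cfg)), collapse = ""))

#' Run the full pipeline on a synthetic study
#'
#' simulate -> preprocess -> EEG features -> HRV features -> ANOVA tables
#' -> classification, writing every result table as CSV under
#' `config$out_dir` together with a manifest (config hash, seed, package
#' version). Rerunning an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return list with `features`, `hrv`, `tables`, `accuracy`, `out_dir`,
#'   invisibly.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cogload] ", ...)
  stage <- "simulate"
  result <- tryCatch({
    say("simulate: generating synthetic study (seed ", config$seed, ")")
    study <- generate_study(design = study_design(config$n_control,
                                                  config$n_experimental),
                            seed = config$seed,
                            effect_size = config$effect_size,
                            subject_cv = config$subject_cv,
                            eeg_duration = config$eeg_duration,
                            ecg_duration = config$ecg_duration)
    stage <- "features"
    say("features: EEG + HRV extraction over ", length(study$cells),
        " cells")
    feats <- study_features(study, epoch_length = config$epoch_length)
    stage <- "stats"
    say("stats: pre/post one-way ANOVA tables")
    tables <- build_comparison_tables(eeg = feats$eeg, hrv = feats$hrv,
                                      scores = study$scores,
                                      eeg_variable = config$eeg_variable)
    stage <- "classify"
    say("classify: SVM + NN per group x session")
    accuracy <- run_workload_classification(
      feats$eeg, fractions = config$split_fractions, seed = config$seed,
      svm_cost = config$svm_cost,
      nn_config = nn_config_default(hidden = config$nn_hidden))
    stage <- "write"
    utils::write.csv(feats$eeg, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(feats$hrv, file.path(config$out_dir, "hrv.csv"),
                     row.names = FALSE)
    utils::write.csv(study$scores, file.path(config$out_dir, "scores.csv"),
                     row.names = FALSE)
    for (nm in c("ecg", "eeg", "scores"))
      if (!is.null(tables[[nm]]))
        utils::write.csv(tables[[nm]],
                         file.path(config$out_dir,
                                   paste0("anova_", nm, ".csv")),
                         row.names = FALSE)
    utils::write.csv(accuracy, file.path(config$out_dir, "accuracy.csv"),
                     row.names = FALSE)
    writeLines(c(
      paste0("config_hash: ", config_hash(config)),
      paste0("seed: ", config$seed),
      paste0("package: cogload ",
             as.character(utils::packageVersion("cogload"))),
      paste0("generated: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
      file.path(config$out_dir, "manifest.txt"))
    list(features = feats$eeg, hrv = feats$hrv, tables = tables,
         accuracy = accuracy, out_dir = config$out_dir)
  }, error = function(e)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  say("done: ", config$out_dir)
  invisible(result)
}
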