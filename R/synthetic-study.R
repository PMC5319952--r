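#' Default study design
#'
#' 25 subjects — 10 control, 15 experimental — each recorded under baseline
#' (BL), low-workload (LWL) and high-workload (HWL) conditions. The
#' experimental group (which receives the breathing intervention) has three
#' sessions (pre, post30, post90); the control group has pre and post30.
#'
#' @param n_control,n_experimental subjects per group.
#' @return data.frame with columns subject, group, session, condition; one
#'   row per recording cell, every (subject, session, condition) unique.
#' @export
study_design <- function(n_control = 10, n_experimental = 15) {
  cells <- function(ids, group, sessions) {
    g <- expand.grid(subject = ids, session = sessions,
                     condition = c("BL", "LWL", "HWL"),
                     stringsAsFactors = FALSE)
    g$group <- rep(group, nrow(g))
    g[, c("subject", "group", "session", "condition")]
  }
  rbind(
    cells(sprintf("C%02d", seq_len(n_control)), "control",
          c("pre", "post30")),
    cells(sprintf("E%02d", seq_len(n_experimental)), "experimental",
          c("pre", "post30", "post90"))
  )
}

# multiplicative effect directions, relative to the pre-session baseline
# condition. Encodes the study's qualitative findings: after the
# intervention the experimental group's alpha and beta rise and its
# sympathovagal balance falls at rest, the control group shows the
# opposite; gamma dips at 30 days and partially recovers at 90; higher
# workload suppresses alpha and raises beta and frontal theta.
cell_multipliers <- function(group, session, condition, e) {
  m <- c(theta = 1, alpha = 1, beta = 1, gamma = 1, lf = 1, hf = 1)
  if (group == "experimental" && session != "pre") {
    m["alpha"] <- 1 + e
    m["beta"]  <- 1 + e
    m["gamma"] <- if (session == "post30") 1 - e else 1 - e / 2
    m["lf"]    <- sqrt(1 - e)      # SVI ~ (lf/hf)^2 in amplitude terms
  }
  if (group == "control" && session != "pre") {
    m["alpha"] <- 1 - e
    m["beta"]  <- 1 - e
    m["gamma"] <- 1 - e
    m["lf"]    <- sqrt(1 + e)
  }
  if (condition == "LWL") {
    m["alpha"] <- m["alpha"] * (1 - e / 2)
    m["beta"]  <- m["beta"] * (1 + e / 2)
    m["theta"] <- m["theta"] * (1 + e / 2)
  } else if (condition == "HWL") {
    m["alpha"] <- m["alpha"] * (1 - e)
    m["beta"]  <- m["beta"] * (1 + e)
    m["theta"] <- m["theta"] * (1 + e)
  }
  m
}

#' Per-cell generator specifications for a study design
#'
#' Expands a design into one EEG and one HRV simulation spec per cell,
#' applying the built-in effect directions (`effect_size` fractional shifts,
#' default 20%) and a per-subject lognormal trait factor (`subject_cv`)
#' that is constant across that subject's sessions and conditions. Child
#' seeds are derived from the master seed by stable hashing of
#' (subject, session, condition), so any cell can be regenerated alone.
#'
#' @param design a [study_design()] data.frame.
#' @param seed master seed.
#' @param effect_size fractional effect magnitude (0 disables all built-in
#'   contrasts — a null study).
#' @param subject_cv lognormal sd of per-subject band/modulation factors.
#' @param eeg_duration EEG seconds per cell.
#' @param ecg_duration ECG seconds per cell (converted to a beat count).
#' @param base_eeg,base_hrv named lists overriding the baseline
#'   [eeg_sim_spec()] / [hrv_sim_spec()] arguments.
#' @return list of cells; each has `meta` (the design row) plus `eeg_spec`
#'   and `hrv_spec`.
#' @export
study_cell_specs <- function(design = study_design(), seed = 1L,
                             effect_size = 0.2, subject_cv = 0.05,
                             eeg_duration = 64, ecg_duration = 300,
                             base_eeg = list(), base_hrv = list()) {
  eeg_defaults <- utils::modifyList(
    list(n_channels = 8, fs = 128, duration = eeg_duration,
         band_amplitudes = c(theta = 6, alpha = 10, beta = 5, gamma = 3),
         noise_exponent = 1, noise_amplitude = 5,
         channel_labels = frontal_channels()),
    base_eeg)
  hrv_defaults <- utils::modifyList(
    list(mean_rr = 850, lf_mod_amplitude = 40, lf_mod_freq = 0.1,
         hf_mod_amplitude = 30, hf_mod_freq = 0.25, jitter_sd = 15),
    base_hrv)
  hrv_defaults$n_beats <- ceiling(ecg_duration * 1000 / hrv_defaults$mean_rr)

  lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    set.seed(hash_seed(row$subject, "trait", master = seed))
    trait <- exp(stats::rnorm(6, sd = subject_cv))
    names(trait) <- c("theta", "alpha", "beta", "gamma", "lf", "hf")
    m <- cell_multipliers(row$group, row$session, row$condition, effect_size)
    amp <- eeg_defaults$band_amplitudes *
      (m[c("theta", "alpha", "beta", "gamma")] *
         trait[c("theta", "alpha", "beta", "gamma")])
    eeg_args <- eeg_defaults
    eeg_args$band_amplitudes <- amp
    eeg_args$seed <- hash_seed(row$subject, row$session, row$condition,
                               "eeg", master = seed)
    hrv_args <- hrv_defaults
    hrv_args$lf_mod_amplitude <- hrv_defaults$lf_mod_amplitude *
      m[["lf"]] * trait[["lf"]]
    hrv_args$hf_mod_amplitude <- hrv_defaults$hf_mod_amplitude *
      m[["hf"]] * trait[["hf"]]
    hrv_args$seed <- hash_seed(row$subject, row$session, row$condition,
                               "ecg", master = seed)
    list(meta = as.list(row),
         eeg_spec = do.call(eeg_sim_spec, eeg_args),
         hrv_spec = do.call(hrv_sim_spec, hrv_args))
  })
}

#' Generate a complete synthetic study
#'
#' One EEG and one ECG [recording()] per design cell (via
#' [study_cell_specs()]), plus a subjective workload-score table for the
#' task conditions. Fully reproducible under the master seed.
#'
#' @inheritParams study_cell_specs
#' @param score_sd between-subject sd of the subjective score.
#' @return list of class `workload_study`: `design`, `cells` (each with
#'   `meta`, `eeg`, `ecg`), `scores` (subject/group/session/condition/
#'   score), `specs` (the per-cell generator specs), `seed`, `effect_size`.
#' @export
generate_study <- function(design = study_design(), seed = 1L,
                           effect_size = 0.2, subject_cv = 0.05,
                           eeg_duration = 64, ecg_duration = 300,
                           base_eeg = list(), base_hrv = list(),
                           score_sd = 8) {
  specs <- study_cell_specs(design, seed = seed, effect_size = effect_size,
                            subject_cv = subject_cv,
                            eeg_duration = eeg_duration,
                            ecg_duration = ecg_duration,
                            base_eeg = base_eeg, base_hrv = base_hrv)
  cells <- lapply(specs, function(cl) {
    eeg <- generate_eeg(cl$eeg_spec)
    eeg$metadata <- cl$meta
    ecg <- generate_ecg(generate_rr_series(cl$hrv_spec),
                        metadata = cl$meta)
    list(meta = cl$meta, eeg = eeg, ecg = ecg)
  })
  # subjective workload scores for the task conditions; the experimental
  # group's post scores drop, the control group drifts slightly (LWL down,
  # HWL up), mirroring the reported direction of subjective relief
  base_score <- c(LWL = 45, HWL = 70)
  scores <- do.call(rbind, lapply(specs, function(cl) {
    meta <- cl$meta
    if (meta$condition == "BL") return(NULL)
    mult <- 1
    if (meta$session != "pre") {
      mult <- if (meta$group == "experimental") 1 - effect_size
              else if (meta$condition == "LWL") 1 - effect_size / 4
              else 1 + effect_size / 4
    }
    set.seed(hash_seed(meta$subject, meta$session, meta$condition,
                       "score", master = seed))
    data.frame(subject = meta$subject, group = meta$group,
               session = meta$session, condition = meta$condition,
               score = base_score[[meta$condition]] * mult +
                 stats::rnorm(1, sd = score_sd),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(design = design, cells = cells, scores = scores, specs = specs,
         seed = as.integer(seed), effect_size = effect_size),
    class = "workload_study")
}

#' @export
print.workload_study <- function(x, ...) {
  cat(sprintf(paste0("<workload_study: %d cells (%d subjects), effect size ",
                     "%.0f%%, seed %d>\n"),
              length(x$cells), length(unique(x$design$subject)),
              100 * x$effect_size, x$seed))
  invisible(x)
}

#' Feature extraction across a whole study
#'
#' Runs [preprocess_recording()] + [extract_features()] on every EEG cell
#' and [preprocess_recording()] + [hrv_pipeline()] on every ECG cell.
#'
#' @param study a `workload_study` from [generate_study()].
#' @param preprocess apply the default conditioning chain first.
#' @param epoch_length EEG epoch seconds.
#' @return list with `eeg` (an `eeg_feature_table`) and `hrv` (one row per
#'   cell).
#' @export
study_features <- function(study, preprocess = TRUE, epoch_length = 4) {
  stopifnot(inherits(study, "workload_study"))
  eeg_rows <- lapply(study$cells, function(cl) {
    rec <- if (preprocess) preprocess_recording(cl$eeg) else cl$eeg
    extract_features(rec, epoch_length = epoch_length)
  })
  hrv_rows <- lapply(study$cells, function(cl) {
    rec <- if (preprocess) preprocess_recording(cl$ecg) else cl$ecg
    suppressWarnings(hrv_pipeline(rec))
  })
  eeg <- do.call(rbind, eeg_rows)
  class(eeg) <- c("eeg_feature_table", "data.frame")
  list(eeg = eeg, hrv = do.call(rbind, hrv_rows))
}
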