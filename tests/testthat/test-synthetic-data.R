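test_that("zero-amplitude spec yields an all-zero recording", {
  spec <- eeg_sim_spec(n_channels = 2, duration = 4,
                       band_amplitudes = c(theta = 0, alpha = 0, beta = 0,
                                           gamma = 0),
                       noise_amplitude = 0, seed = 1)
  rec <- generate_eeg(spec)
  expect_equal(dim(rec$samples), c(2, 512))
  expect_true(all(rec$samples == 0))
})

test_that("EEG generation is deterministic under a fixed seed", {
  spec <- eeg_sim_spec(n_channels = 3, duration = 5, seed = 99)
  expect_identical(generate_eeg(spec)$samples, generate_eeg(spec)$samples)
  spec2 <- eeg_sim_spec(n_channels = 3, duration = 5, seed = 100)
  expect_false(identical(generate_eeg(spec)$samples,
                         generate_eeg(spec2)$samples))
})

test_that("requested band dominates the generated spectrum", {
  spec <- eeg_sim_spec(n_channels = 1, duration = 30,
                       band_amplitudes = c(theta = 1, alpha = 10, beta = 1,
                                           gamma = 1),
                       noise_amplitude = 0, seed = 7)
  x <- channel_data(generate_eeg(spec), 1)
  bands <- eeg_bands()
  bp <- vapply(seq_len(4), function(k)
    oracle_fft_band_power(x, 128, bands$low[k], bands$high[k]), numeric(1))
  expect_identical(which.max(bp), 2L)  # alpha
})

test_that("single-band spec concentrates >= 80% of 4-45 Hz power in band", {
  for (k in seq_len(4)) {
    amps <- c(theta = 0, alpha = 0, beta = 0, gamma = 0)
    amps[k] <- 8
    spec <- eeg_sim_spec(n_channels = 1, duration = 30,
                         band_amplitudes = amps, noise_amplitude = 0,
                         seed = k)
    x <- channel_data(generate_eeg(spec), 1)
    psd <- welch_psd(x, 128, 256)
    b <- eeg_bands()[k, ]
    frac <- band_power(psd, b$low, b$high) / band_power(psd, 4, 45)
    expect_gt(frac, 0.8)
  }
})

test_that("Nyquist violations and bad amplitudes are rejected", {
  expect_error(eeg_sim_spec(fs = 60), "Nyquist")
  expect_error(eeg_sim_spec(band_amplitudes = c(alpha = -1)), "amplitudes")
  expect_error(eeg_sim_spec(duration = 0), "duration")
})

test_that("RR generation honours its tachogram model", {
  const <- hrv_sim_spec(mean_rr = 1000, n_beats = 10, lf_mod_amplitude = 0,
                        hf_mod_amplitude = 0, jitter_sd = 0)
  expect_equal(generate_rr_series(const)$intervals, rep(1000, 10))

  spec <- hrv_sim_spec(mean_rr = 850, n_beats = 300, seed = 5)
  rr <- generate_rr_series(spec)
  expect_lt(abs(mean(rr$intervals) - 850) / 850, 0.02)
  expect_true(all(rr$intervals > 0))
  expect_identical(rr$intervals, generate_rr_series(spec)$intervals)
})

test_that("LF-only modulation produces an LF-dominant tachogram spectrum", {
  spec <- hrv_sim_spec(mean_rr = 850, n_beats = 360, lf_mod_amplitude = 50,
                       hf_mod_amplitude = 0, jitter_sd = 0, seed = 1)
  fd <- suppressWarnings(frequency_domain_hrv(generate_rr_series(spec)))
  expect_gt(fd$lf_power / fd$hf_power, 10)
})

test_that("jitter-free single modulation peaks within one bin of its freq", {
  for (f0 in c(0.08, 0.25)) {
    spec <- hrv_sim_spec(mean_rr = 800, n_beats = 400,
                         lf_mod_amplitude = if (f0 < 0.15) 50 else 0,
                         lf_mod_freq = max(0.04, min(f0, 0.15)),
                         hf_mod_amplitude = if (f0 >= 0.15) 50 else 0,
                         hf_mod_freq = max(0.15, min(f0, 0.4)),
                         jitter_sd = 0, seed = 2)
    rr <- generate_rr_series(spec)
    t_beat <- rr$beat_times[-1] / 1000
    grid <- seq(min(t_beat), max(t_beat), by = 0.25)
    tach <- stats::spline(t_beat, rr$intervals, xout = grid)$y
    psd <- welch_psd(tach - mean(tach), fs = 4,
                     segment_length = length(tach), overlap_fraction = 0)
    peak_f <- psd$freq[which.max(psd$power)]
    expect_lt(abs(peak_f - f0), psd$freq[2] - psd$freq[1] + 1e-12)
  }
})

test_that("invalid tachogram parameters are rejected", {
  expect_error(hrv_sim_spec(mean_rr = -5), "mean_rr")
  expect_error(hrv_sim_spec(n_beats = 1), "n_beats")
  expect_error(hrv_sim_spec(lf_mod_amplitude = 500, hf_mod_amplitude = 400,
                            mean_rr = 850), "nonpositive")
  expect_error(hrv_sim_spec(lf_mod_freq = 0.2), "lf_mod_freq")
})

test_that("synthetic ECG carries exact ground truth", {
  rr <- rr_series(rep(1000, 20))
  ecg <- generate_ecg(rr, fs = 500)
  truth <- ecg$metadata$r_peaks
  expect_length(truth, 21)                      # n intervals -> n+1 peaks
  expect_equal(diff(truth), round(rr$intervals * 500 / 1000))
  # each beat's local argmax coincides with the stored R index (+/- 1)
  x <- channel_data(ecg, 1)
  for (p in truth) {
    lo <- max(1, p - 50); hi <- min(length(x), p + 50)
    expect_lte(abs(lo + which.max(x[lo:hi]) - 1 - p), 1)
  }
})

test_that("quantized ground-truth spacing stays within one sample of RR", {
  spec <- hrv_sim_spec(mean_rr = 870.3, n_beats = 50, seed = 3)
  rr <- generate_rr_series(spec)
  ecg <- generate_ecg(rr, fs = 500)
  spacing <- diff(ecg$metadata$r_peaks)
  expect_true(all(abs(spacing - round(rr$intervals * 500 / 1000)) <= 1))
})

test_that("overlapping beat templates are rejected", {
  expect_error(generate_ecg(rr_series(rep(400, 10)), fs = 500), "wider")
  expect_error(generate_ecg(rr_series(rep(1000, 5)), fs = 200), "fs")
})

test_that("default study matches the cohort layout", {
  design <- study_design()
  expect_length(unique(design$subject), 25)
  expect_length(unique(design$subject[design$group == "control"]), 10)
  expect_length(unique(design$subject[design$group == "experimental"]), 15)
  # control: pre/post30 only; experimental: all three sessions
  expect_setequal(unique(design$session[design$group == "control"]),
                  c("pre", "post30"))
  expect_setequal(unique(design$session[design$group == "experimental"]),
                  c("pre", "post30", "post90"))
  expect_false(any(duplicated(design[, c("subject", "session",
                                         "condition")])))
})

test_that("study specs encode the built-in effect directions", {
  specs <- study_cell_specs(seed = 1, subject_cv = 0)
  meta <- do.call(rbind, lapply(specs, function(s) as.data.frame(s$meta)))
  pick <- function(grp, ses, cond) {
    i <- which(meta$group == grp & meta$session == ses &
                 meta$condition == cond)[1]
    specs[[i]]
  }
  pre  <- pick("experimental", "pre", "BL")
  post <- pick("experimental", "post30", "BL")
  expect_gt(post$eeg_spec$band_amplitudes[["alpha"]],
            pre$eeg_spec$band_amplitudes[["alpha"]])
  expect_gt(post$eeg_spec$band_amplitudes[["beta"]],
            pre$eeg_spec$band_amplitudes[["beta"]])
  # SVI target down: LF modulation shrinks while HF is unchanged
  expect_lt(post$hrv_spec$lf_mod_amplitude / post$hrv_spec$hf_mod_amplitude,
            pre$hrv_spec$lf_mod_amplitude / pre$hrv_spec$hf_mod_amplitude)
  cpre  <- pick("control", "pre", "BL")
  cpost <- pick("control", "post30", "BL")
  expect_lt(cpost$eeg_spec$band_amplitudes[["alpha"]],
            cpre$eeg_spec$band_amplitudes[["alpha"]])
  # HWL suppresses alpha, raises beta and theta, within a session
  bl  <- pick("experimental", "pre", "BL")
  hwl <- pick("experimental", "pre", "HWL")
  expect_lt(hwl$eeg_spec$band_amplitudes[["alpha"]],
            bl$eeg_spec$band_amplitudes[["alpha"]])
  expect_gt(hwl$eeg_spec$band_amplitudes[["beta"]],
            bl$eeg_spec$band_amplitudes[["beta"]])
  expect_gt(hwl$eeg_spec$band_amplitudes[["theta"]],
            bl$eeg_spec$band_amplitudes[["theta"]])
})

test_that("study generation is reproducible cell by cell", {
  design <- study_design(2, 2)
  s1 <- generate_study(design, seed = 3, eeg_duration = 8, ecg_duration = 60)
  s2 <- generate_study(design, seed = 3, eeg_duration = 8, ecg_duration = 60)
  expect_identical(s1$cells[[5]]$eeg$samples, s2$cells[[5]]$eeg$samples)
  expect_identical(s1$cells[[5]]$ecg$samples, s2$cells[[5]]$ecg$samples)
  expect_identical(s1$scores, s2$scores)
  # child seeds depend on the cell key, not on generation order
  sub <- generate_study(design[5, ], seed = 3, eeg_duration = 8,
                        ecg_duration = 60)
  expect_identical(sub$cells[[1]]$eeg$samples, s1$cells[[5]]$eeg$samples)
})
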