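test_that("RMS matches its closed forms and a brute-force oracle", {
  expect_equal(signal_rms(rep(3, 17)), 3)
  t <- seq(0, 5, by = 1 / 200)[-1]            # integer number of cycles
  expect_equal(signal_rms(sin(2 * pi * 4 * t)), 1 / sqrt(2),
               tolerance = 1e-6)
  set.seed(4)
  x <- rnorm(321)
  brute <- sqrt(sum(vapply(x, function(v) v^2, numeric(1))) / length(x))
  expect_equal(signal_rms(x), brute)
  expect_error(signal_rms(numeric(0)), "empty")
})

test_that("DWT energies localize a pure tone at the right level", {
  t <- seq_len(512) / 128
  be <- dwt_band_energies(sin(2 * pi * 10 * t), fs = 128)
  expect_identical(names(which.max(be$energy)), "alpha")  # D3 = 8-16 Hz
  # dominant level agrees with an FFT-bandpass oracle on the dyadic ranges,
  # for a tone in each level's band
  for (f0 in c(6, 10, 20, 40)) {
    x <- sin(2 * pi * f0 * t)
    bex <- dwt_band_energies(x, fs = 128)
    oracle <- vapply(seq_len(4), function(k) {
      b <- bex$level_bands[5 - k, ]           # theta..gamma order
      oracle_fft_band_power(x, 128, b$low, b$high)
    }, numeric(1))
    expect_identical(unname(which.max(bex$energy)), which.max(oracle))
  }
})

test_that("DWT satisfies Parseval and flags degenerate epochs", {
  set.seed(11)
  x <- rnorm(512)
  be <- dwt_band_energies(x, fs = 128)
  expect_lt(abs(be$e_tot - sum(x^2)) / sum(x^2), 0.01)
  z <- dwt_band_energies(rep(0, 512), fs = 128)
  expect_true(z$degenerate)
  expect_true(all(z$energy == 0) && all(z$pl == 0))
  expect_error(dwt_db4(rnorm(8), levels = 4), "too short")
})

test_that("Welch PSD matches the independent segment-FFT oracle", {
  set.seed(21)
  for (rep_i in 1:5) {
    x <- rnorm(700 + rep_i * 13)
    mine <- welch_psd(x, fs = 128, segment_length = 256)
    orac <- oracle_welch(x, fs = 128, L = 256)
    expect_equal(mine$freq, orac$freq)
    expect_lt(max(abs(mine$power - orac$power)) / max(orac$power), 1e-10)
  }
})

test_that("Welch PSD integrates to the variance and peaks at the tone", {
  set.seed(31)
  x <- rnorm(128 * 60)
  psd <- welch_psd(x, fs = 128, segment_length = 256)
  total <- band_power(psd, 0, 64)
  expect_lt(abs(total - var(x)) / var(x), 0.10)

  t <- seq_len(128 * 8) / 128
  p10 <- welch_psd(sin(2 * pi * 10 * t), fs = 128, segment_length = 256)
  expect_lt(abs(p10$freq[which.max(p10$power)] - 10), 128 / 256 + 1e-12)
  expect_error(welch_psd(rnorm(100), 128, segment_length = 256), "exceeds")
})

test_that("band_power integrates the density correctly", {
  flat <- structure(list(freq = seq(0, 64, by = 0.5),
                         power = rep(1, 129)), class = "psd_estimate")
  expect_equal(band_power(flat, 8, 13), 5)
  zero <- structure(list(freq = seq(0, 64, by = 0.5),
                         power = rep(0, 129)), class = "psd_estimate")
  expect_equal(band_power(zero, 8, 13), 0)
  set.seed(5)
  psd <- welch_psd(rnorm(2048), 128, 256)
  bands <- eeg_bands()
  four <- sum(vapply(seq_len(4), function(k)
    band_power(psd, bands$low[k], bands$high[k]), numeric(1)))
  expect_lte(four, band_power(psd, 0, 64) + 1e-12)
  expect_error(band_power(psd, 60, 70), "outside")
})

test_that("engagement index follows its defining ratio", {
  expect_equal(engagement_index(1, 1, 1), 0.5)
  expect_equal(engagement_index(1, 1, 0), 0)
  expect_equal(engagement_index(3, 1, 2), 0.5)
  expect_error(engagement_index(0, 0, 1), "undefined")
  # strictly increasing in beta with alpha/theta fixed
  eis <- vapply(c(1, 2, 5, 9), function(b) engagement_index(2, 3, b),
                numeric(1))
  expect_true(all(diff(eis) > 0))
})

test_that("feature extraction epochs, composes and flags correctly", {
  spec <- eeg_sim_spec(n_channels = 2, duration = 8 * 60, seed = 2,
                       channel_labels = c("AF3", "F4"))
  rec <- generate_eeg(spec)
  feats <- extract_features(rec, epoch_length = 4)
  expect_equal(nrow(feats), 2 * 120)          # 8 min / 4 s = 120 epochs
  expect_equal(max(feats$epoch), 120)
  # EI column is the row-wise engagement index of the band-power columns
  expect_equal(feats$ei,
               mapply(engagement_index, feats$p_theta, feats$p_alpha,
                      feats$p_beta))
  expect_false(any(!is.finite(as.matrix(
    feats[, c("e_theta", "p_alpha", "rms", "ei")]))))
  expect_error(extract_features(rec, channels = c("AF3", "XX")), "XX")
})

test_that("alpha-dominant recordings yield alpha-dominant features", {
  spec <- eeg_sim_spec(n_channels = 1, duration = 60,
                       band_amplitudes = c(theta = 2, alpha = 12,
                                           beta = 2, gamma = 1),
                       noise_amplitude = 1, seed = 6,
                       channel_labels = "F3")
  feats <- extract_features(generate_eeg(spec))
  pls <- colMeans(feats[, c("pl_theta", "pl_alpha", "pl_beta", "pl_gamma")])
  expect_identical(names(which.max(pls)), "pl_alpha")
})

test_that("features transform correctly under amplitude scaling", {
  spec <- eeg_sim_spec(n_channels = 1, duration = 16, seed = 9,
                       channel_labels = "F7")
  rec <- generate_eeg(spec)
  k <- 3.7
  scaled <- rec; scaled$samples <- k * scaled$samples
  f1 <- extract_features(rec); f2 <- extract_features(scaled)
  expect_equal(f2$e_alpha, k^2 * f1$e_alpha, tolerance = 1e-8)
  expect_equal(f2$rms, k * f1$rms, tolerance = 1e-10)
  expect_equal(f2$ei, f1$ei, tolerance = 1e-8)
  expect_equal(f2$pl_beta, f1$pl_beta, tolerance = 1e-8)
})

test_that("dead-channel epochs are flagged, not fatal", {
  rec <- recording(matrix(0, nrow = 1, ncol = 1024), fs = 128,
                   channel_labels = "FC5")
  feats <- extract_features(rec)
  expect_true(all(feats$degenerate))
  expect_true(all(feats$ei == 0))
})
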