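# Independent oracles used to validate the package's own implementations.
# Each is written from the textbook definition, structured differently from
# the code under test (explicit loops, DFT matrices), and is never called
# by the package itself.

# Welch PSD by explicit segment extraction and a DFT-matrix multiply
oracle_welch <- function(x, fs, L, overlap = 0.5, window = "hamming",
                         detrend = TRUE) {
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)),
    hann    = 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1))),
    rect    = rep(1, L))
  k <- 0:(L %/% 2)
  dft <- exp(-2i * pi * outer(k, 0:(L - 1)) / L)   # one-sided DFT matrix
  step <- L - round(overlap * L)
  starts <- seq(1, length(x) - L + 1, by = step)
  acc <- numeric(length(k))
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    if (detrend) seg <- seg - mean(seg)
    X <- dft %*% (seg * w)
    pg <- Mod(X)^2 / (fs * sum(w^2))
    scale2 <- rep(2, length(k)); scale2[1] <- 1
    if (L %% 2 == 0) scale2[length(k)] <- 1
    acc <- acc + pg * scale2
  }
  list(freq = k * fs / L, power = acc / length(starts))
}

# band power of a signal by plain periodogram summation (rank-order oracle)
oracle_fft_band_power <- function(x, fs, low, high) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / n^2
  f <- (0:(n - 1)) * fs / n
  sel <- f >= low & f < high
  2 * sum(pg[sel & f <= fs / 2])
}

# NN50 by explicit loop over successive interval pairs
oracle_nn50 <- function(intervals) {
  count <- 0L
  for (i in seq_len(length(intervals) - 1)) {
    if (abs(intervals[i + 1] - intervals[i]) > 50) count <- count + 1L
  }
  count
}

# one-way ANOVA F by the hand sum-of-squares formula
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- sum(sapply(groups, function(g) length(g) * (mean(g) - gm)^2))
  ss_w <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# fraction of ground-truth peaks matched by a detection within tol_ms
match_fraction <- function(detected, truth, fs, tol_ms = 20) {
  if (!length(detected)) return(0)
  tol <- tol_ms / 1000 * fs
  hits <- vapply(truth, function(p) any(abs(detected - p) <= tol), logical(1))
  mean(hits)
}

# small balanced Gaussian-cloud feature set for classifier checks
make_clouds <- function(n = 200, d = 8, sep = 5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n / 2 * d), ncol = d),
             matrix(stats::rnorm(n / 2 * d, mean = sep), ncol = d))
  labeled_features(x, rep(c("LWL", "HWL"), each = n / 2))
}
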