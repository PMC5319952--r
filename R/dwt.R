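# Daubechies-4 (8-tap, four vanishing moments) orthogonal filter bank.
# Standard published coefficients; hi-pass is the quadrature mirror.
DB4_LO <- c(-0.010597401785069032,  0.0328830116668852,
             0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854,  0.6308807679298589,
             0.7148465705529157,    0.2303778133088965)
DB4_HI <- rev(DB4_LO) * c(-1, 1, -1, 1, -1, 1, -1, 1)

# one periodized analysis step: returns approximation and detail
# coefficients of length ceiling(n/2). Periodization keeps the transform
# orthogonal, so coefficient energies satisfy Parseval exactly.
dwt_step <- function(x, lo = DB4_LO, hi = DB4_HI) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[1]); n <- n + 1 }  # periodic pad to even
  L <- length(lo)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], ncol = L)
  list(a = as.numeric(xm %*% lo), d = as.numeric(xm %*% hi))
}

#' Multilevel discrete wavelet decomposition (Daubechies-4, periodized)
#'
#' Pyramid analysis with the orthogonal db4 filter bank and periodic signal
#' extension. Orthogonality means the squared coefficients partition the
#' signal's energy: sum of squares over all details plus the final
#' approximation equals `sum(x^2)` (Parseval), which is what makes
#' wavelet band energies additive.
#'
#' @param x numeric vector, length >= 2^levels.
#' @param levels decomposition depth.
#' @return list with `details` (list of coefficient vectors, level 1 =
#'   finest/highest frequencies) and `approx` (final approximation).
#' @export
dwt_db4 <- function(x, levels = 4) {
  if (length(x) < 2^levels)
    stop("signal of length ", length(x), " is too short for ", levels,
         " decomposition levels (need >= ", 2^levels, ")")
  details <- vector("list", levels)
  a <- as.numeric(x)
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(details = details, approx = a)
}

#' Wavelet band energies of an EEG epoch
#'
#' Decomposes a single channel with [dwt_db4()] and maps detail levels to
#' the canonical bands by their dyadic frequency ranges. At the native
#' 128 Hz rate: D1 = 32-64 Hz (gamma proxy), D2 = 16-32 Hz (beta proxy),
#' D3 = 8-16 Hz (alpha proxy), D4 = 4-8 Hz (theta); the final approximation
#' A4 holds 0-4 Hz. Band energy is the sum of squared detail coefficients
#' (equal, for an orthogonal wavelet, to the energy of the reconstructed
#' detail signal); the total energy is the sum over every decomposition
#' component, and normalized energies are `Pl = E_band / E_tot`.
#'
#' The dyadic edges (16/32/64) do not coincide exactly with the 13/30/45 Hz
#' band definitions; exact band powers are available via the Welch path
#' ([band_power()]). Use these energies as the wavelet-domain feature set.
#'
#' @param x single-channel samples.
#' @param fs sampling rate, Hz; 128 gives the canonical level-to-band map.
#' @param levels decomposition depth (default 4).
#' @return list of class `band_energies`: `energy` (named: theta, alpha,
#'   beta, gamma), `e_tot`, `pl` (normalized, zero with `degenerate = TRUE`
#'   for an all-zero epoch), `e_approx`, `fs`, and `level_bands` (the dyadic
#'   Hz range each level covers).
#' @examples
#' t <- seq(0, 4, by = 1/128)[-1]
#' be <- dwt_band_energies(sin(2 * pi * 10 * t), fs = 128)
#' names(which.max(be$energy))  # "alpha" (10 Hz lies in D3 = 8-16 Hz)
#' @export
dwt_band_energies <- function(x, fs = 128, levels = 4) {
  if (levels < 4) stop("need >= 4 levels to cover theta through gamma")
  if (fs / 2^(levels + 1) > 4 + 1e-9 || fs / 4 < 30)
    warning("level-to-band map assumes fs = 128; got fs = ", fs)
  dec <- dwt_db4(x, levels = levels)
  e_detail <- vapply(dec$details, function(d) sum(d^2), numeric(1))
  e_approx <- sum(dec$approx^2)
  e_tot <- sum(e_detail) + e_approx
  # D1 highest frequency: map finest->gamma ... level 4 -> theta
  bands <- c("gamma", "beta", "alpha", "theta")
  energy <- stats::setNames(e_detail[seq_len(4)], bands)[
    c("theta", "alpha", "beta", "gamma")]
  degenerate <- e_tot == 0
  pl <- if (degenerate) stats::setNames(rep(0, 4), names(energy))
        else energy / e_tot
  edges <- fs / 2^(seq_len(levels) + 1)
  structure(
    list(energy = energy, e_tot = e_tot, pl = pl, e_approx = e_approx,
         degenerate = degenerate, fs = fs,
         level_bands = data.frame(level = paste0("D", seq_len(levels)),
                                  low = edges, high = edges * 2)),
    class = "band_energies"
  )
}

#' @export
print.band_energies <- function(x, ...) {
  cat("<band_energies>\n")
  print(round(rbind(energy = x$energy, pl = x$pl), 4))
  cat("  e_tot =", format(x$e_tot), if (x$degenerate) " (degenerate)" else "",
      "\n")
  invisible(x)
}
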