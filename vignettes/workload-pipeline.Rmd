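---
title: "Quantifying mental workload from EEG and ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mental workload from EEG and ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogload)
```

## The problem

Sustained multitasking drives a characteristic physiological signature:
as task load rises, EEG beta power increases, frontal theta increases and
alpha is suppressed, while the heart's beat-to-beat variability shifts
toward sympathetic dominance. `cogload` implements a complete analysis
chain for studies that track these markers across groups (e.g. a breathing
intervention vs. control), sessions (pre, post 30 days, post 90 days) and
workload conditions (rest baseline BL, low workload LWL, high workload
HWL): feature extraction from raw EEG and ECG, one-way ANOVA comparison
tables, and LWL-vs-HWL classification.

Because subject recordings in this design are rarely shareable, the
package carries a first-class synthetic-data generator that reproduces the
*structure* of such a study — band-limited EEG with controllable band
power, ECG synthesized from a controllable RR tachogram, and a whole-study
builder that encodes the qualitative effect directions reported in this
literature. Every downstream stage is validated against it.

## EEG features

**Bands.** theta 4–8 Hz, alpha 8–13 Hz, beta 13–30 Hz, gamma 30–45 Hz
(half-open intervals, gamma closing at 45 Hz).

**Wavelet band energies.** `dwt_band_energies()` decomposes each epoch
with an orthogonal Daubechies-4 (8-tap) DWT with periodic extension.
Orthogonality is the load-bearing property: the squared coefficients
partition the epoch's energy exactly (Parseval), so band energies are
additive and the normalized energies `Pl = E_band / E_tot` lie in [0, 1]
and sum (with the approximation term) to 1. A Morlet continuous transform
has better time-frequency localization but no such energy partition, which
is why the discrete orthogonal family is used here. At the native 128 Hz
rate the dyadic detail levels cover D1 = 32–64, D2 = 16–32, D3 = 8–16,
D4 = 4–8 Hz. The 16/32/64 Hz edges do not coincide exactly with the
13/30/45 Hz band definitions; this is an unavoidable property of dyadic
decompositions, so the wavelet energies are treated as the wavelet-domain
feature set while *exact* band powers always come from the Welch path.

**Welch PSD.** `welch_psd()` averages modified periodograms:
`I(ω) = |FFT(x·w)|² / (fs·L·U)` with `U = Σw²/L`, one-sided density
scaling. Defaults inside `extract_features()`: 256-sample (2 s) segments,
50 % overlap, Hamming window, per-segment mean removal. Band powers are
trapezoidal integrals of the density with interpolated band edges, so a
flat unit density integrates to exactly the band width.

**Engagement index.** `EI = β/(α + θ)` on Welch band powers (the index is
defined in PSD terms, so the wavelet energies are not used here). EI is
scale-invariant — multiplying the signal by k multiplies every band power
by k² and leaves EI unchanged — which makes it robust to per-subject
amplitude differences and is the reason it is the classification feature.

**Epoching.** 4-s non-overlapping epochs. Four seconds at 128 Hz gives 512
samples: enough for 3 Welch segments and 4 clean DWT levels, short enough
to yield many classification rows per recording. All-zero epochs (dead
channels) produce flagged zero rows rather than errors so that batch runs
survive.

**Channels.** The eight frontal/fronto-central 10–20 sites
(AF3, F7, F3, FC5, FC6, F4, F8, AF4) are the default analysis set, these
being the sites most directly tied to workload variance; any channel list
can be passed.

## ECG features

**QRS detection.** `pan_tompkins()` implements the classic chain —
5–15 Hz bandpass, five-point derivative, squaring, 150 ms moving-window
integration, adaptive dual thresholds with running signal/noise levels, a
200 ms refractory period and a search-back at 1.66× the running RR
average. Thresholds are initialized from the first 2 s of the integrated
signal. Because filtering here is zero-phase, the integrated peak sits on
a broad plateau rather than trailing the QRS at a fixed delay; detection
therefore refines each candidate in two steps (argmax of the bandpassed
signal within the integration window, then the local raw-waveform maximum
within ±50 ms). All thresholds are relative, so detection is invariant to
positive amplitude scaling, and indices shift exactly with time shifts.

**HRV.** RR intervals are `(x_{i+1} − x_i)/fs` in ms. Time domain:
mean RR; NN50 = successive pairs differing by more than 50 ms; pNN50 =
100·NN50/pairs. (The denominator is the number of successive pairs — the
standard definition — not the sum of the intervals.) Frequency domain: the
tachogram is cubic-spline interpolated to a uniform 4 Hz grid,
mean-detrended, Welch-analysed (120-s segments, 50 % overlap) and
integrated over LF 0.04–0.15 Hz and HF 0.15–0.4 Hz; the sympathovagal
balance index is SVI = LF/HF. Durations under 60 s are rejected (the LF
band cannot be resolved at all) and under 250 s a warning flags unstable
LF estimates. No ectopic-beat cleaning is applied; intervals outside
300–2000 ms only raise a flag on the series.

## Statistics

`one_way_anova()` is the classical between/within decomposition
(`stats::oneway.test` with equal variances); degenerate inputs resolve
explicitly (identical groups → F = 0, p = 1; zero within-group variance
with a real difference → F = ∞ flagged). `build_comparison_tables()`
mirrors the study layout: per group × condition, pre vs. post session as
independent groups. Treating a repeated measure this way is a documented
simplification that matches how such tables are typically reported; it is
conservative when subjects are consistent across sessions. Per-epoch EEG
features are first averaged to one value per subject × channel ×
condition × session so that epochs do not masquerade as subjects
(pseudo-replication); the ANOVA degrees of freedom reflect subjects. No
multiple-testing correction drives the significance stars (matching the
reporting convention the tables mirror), but a Benjamini–Hochberg column
is emitted alongside for readers who want it.

## Classification

Rows are epochs; features are the eight per-channel engagement indices;
labels are LWL/HWL. `split_dataset()` makes label-stratified 20/15/65
train/validation/test partitions — an unusual allocation (only 20 %
training data) kept as the default because it is the design being
reproduced; any fractions can be passed. Both classifiers standardize
features with training-set statistics.

The SVM is the soft-margin RBF machine (`e1071`/libsvm), default C = 1
and the libsvm bandwidth heuristic γ = 1/(d·var). The neural network is a
single hidden layer of 10 logistic units trained by error
back-propagation on the mean cross-entropy — full-batch gradient descent
with classical momentum 0.9 and learning rate 0.5, the validation
partition providing early stopping (patience 20, best-validation weights
restored). Plain gradient descent without momentum needs a far smaller
step for stability and then cannot solve even XOR within the 500-epoch
cap; momentum at this step size solves XOR and the separable benchmarks
comfortably while remaining a pure gradient-descent method. Weight
initialization, the split and libsvm are all deterministic under the
supplied seeds, so classification results reproduce exactly.

## The synthetic-data generator

**EEG.** Each channel is a sum of band-limited oscillations — white noise
bandpass-filtered (4th-order Butterworth) to each band and rescaled to a
requested RMS amplitude — plus 1/f background noise made by spectral
shaping of white noise (exponent 1 by default). Broadband band content,
rather than single sinusoids, is deliberate: Welch and wavelet estimators
then behave as they do on real EEG. Defaults (theta 6, alpha 10, beta 5,
gamma 3 µV RMS over 5 µV of 1/f noise) give the resting alpha-dominant
spectrum of an adult frontal channel. A single-band spec concentrates
≥ 80 % of its 4–45 Hz power in the requested band.

**ECG.** An RR tachogram `RR_i = mean_rr + A_lf·sin(2π f_lf t_i) +
A_hf·sin(2π f_hf t_i) + jitter` (defaults: 850 ms mean, 40 ms at 0.1 Hz,
30 ms at 0.25 Hz, 15 ms white jitter) drives a beat-template synthesizer:
Gaussian P/Q/R/S/T bumps with typical lead-II morphology (R 1 mV
dominant positive, 80 ms QRS, P 0.15 mV, T 0.3 mV). True R-peak indices
are returned as ground truth, which is what makes detector recovery a
measurable quantity.

**Study builder.** `generate_study()` expands the 10-control /
15-experimental design (control: pre + post30; experimental: pre +
post30 + post90; BL/LWL/HWL each) into per-cell specs. Effect directions
are multiplicative, default magnitude 20 %: post-intervention experimental
rest gains alpha and beta and loses LF modulation (SVI down); the control
group drifts the opposite way; higher workload suppresses alpha and
raises beta and theta (LWL at half strength). The 20 % magnitude is a
configurable package default — the literature this emulates reports
directions, not magnitudes. Per-subject lognormal trait factors (5 % CV)
give realistic between-subject spread while staying constant within a
subject. Child seeds come from a stable hash of
(subject, session, condition), so any cell regenerates identically in
isolation and independent of generation order.

**What the generator does not emulate.** No eye-blink/EMG artifacts, no
non-stationarity within a recording, no ectopic beats, no 12-lead ECG, no
volume-conduction correlation between channels (channels are independent
realisations). Passing tests therefore demonstrate that the *estimators
and pipeline logic* are correct under known ground truth — not that the
pipeline is robust to every artifact of real recordings.

## Simulation sizes and numerical choices

Default synthetic recordings are 64 s of EEG (16 epochs per cell) and
300 s of ECG per cell — sizes chosen so a full 25-subject study (195
cells) generates and analyses in a few minutes while every estimator
still operates well inside its validity range (300 s comfortably exceeds
the 250 s LF-stability guideline). The acquisition-chain filters are
applied zero-phase (forward–backward), a deliberate deviation from the
causal hardware filters they mirror: zero-phase filtering preserves the
alignment of epoch-boundary features at the cost of being non-causal,
which is irrelevant offline. Filter edge transients are absorbed by
odd-reflection padding sized to ~3 time constants of the slowest pole.
The EEG bandpass corners default to 4–45 Hz (the full analysed range; the
emulated acquisition chain specifies the filter type and order but not
its corners) and the notch quality factor to 30. Welch and DWT choices
are stated above; PSD band integrals use trapezoids with interpolated
edges; ties in stratified splitting are resolved by largest remainder
with a global adjustment so partition sizes are exact.

## Known limitations

Pre/post contrasts use independent-groups ANOVA rather than
repeated-measures models; per-channel tables are uncorrected (by design,
with BH emitted alongside); the EDF writer/reader covers the continuous
16-bit subset of the format only; and no claim is made that synthetic
effect magnitudes match any real intervention — only their directions are
encoded.
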