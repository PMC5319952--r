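Package: cogload
Title: EEG and ECG Feature Pipelines for Mental-Workload Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying mental workload from simultaneous EEG and
    ECG recordings. Implements discrete-wavelet band energies, RMS, Welch
    power spectral density, band powers and the engagement index
    beta/(alpha+theta) for EEG; Pan-Tompkins QRS detection, RR tachograms and
    time/frequency-domain heart-rate-variability features (mean RR, NN50,
    pNN50, LF, HF, sympathovagal balance index) for ECG; one-way ANOVA
    comparison tables across study groups and workload conditions; and
    low-vs-high workload classification with an RBF support vector machine
    and a back-propagation neural network. A seeded synthetic-data generator
    produces EEG with prescribed band-power structure and ECG from RR
    tachograms with prescribed spectral modulation, so every stage of the
    pipeline can be exercised and validated without access to subject
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
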