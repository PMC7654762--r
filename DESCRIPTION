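Package: pacr
Title: Phase-Amplitude Coupling Analysis for Electrophysiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and statistical assessment of phase-amplitude coupling
    (PAC) in multi-epoch electrophysiological recordings. Implements six
    coupling estimators (mean vector length, the Kullback-Leibler modulation
    index, heights ratio, normalized direct PAC, phase-locking value and
    Gaussian-copula mutual information) over full comodulogram grids with a
    vectorised evaluation path contractually equal to a per-pair reference
    loop, surrogate-based correction and non-parametric inference (block swap,
    time lag, trial swap; z-score correction; maximum-statistics family-wise
    control), time-resolved event-related PAC via circular-linear correlation,
    preferred-phase estimation, Welch power spectra, inter-trial coherence,
    triangular frequency-bound optimisation, peak-locked time-frequency
    realignment, an augmented Dickey-Fuller stationarity check, and synthetic
    signal generators with controllable coupling for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
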