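Package: interopipe
Title: Cardiorespiratory and fNIRS Analysis of Interoceptive Task Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multimodal interoception experiments
    combining ECG, respiratory-belt, and frontal fNIRS recordings. Detects
    R-peaks and inhalation peaks by template matching with ectopic-interval
    correction, derives instantaneous heart and breathing rates (1/IBI),
    estimates heart-rate-variability spectra with Burg's autoregressive
    method, quantifies cardiorespiratory coupling as the maximum-magnitude
    lagged Spearman cross-correlation, converts dual-wavelength optical
    densities to oxyhemoglobin via the modified Beer-Lambert law, computes
    Spearman channel connectivity, extracts breathing-locked hemodynamic
    components by PCA, and provides the paired nonparametric statistical
    layer (Wilcoxon with Monte-Carlo permutation correction, Friedman,
    Bonferroni over channels). A synthetic-data module generates
    protocol-structured recordings with known ground truth (IPFM heartbeats
    with respiratory sinus arrhythmia, paced-breathing schedules, forward
    fNIRS mixtures) so every stage is testable without human data.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
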