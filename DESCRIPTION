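Package: burstconv
Title: Beta-Burst Kernel Convolution Features for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transient beta-band (15-30 Hz) bursts in epoched EEG via
    superlet time-frequency decomposition and iterative 2D-Gaussian peak
    removal, builds a PCA space of burst waveform shapes, selects the waveform
    axes whose lateralized baseline-to-task modulation is maximal, and derives
    convolution kernels from the extreme waveform groups. Kernel-convolved (or
    band-filtered) signals are spatially filtered with common spatial patterns
    (CSP), and left- versus right-hand motor imagery is decoded with
    time-resolved cross-validated linear discriminant analysis. Includes an
    information transfer rate metric, threshold-stepped cluster-based
    permutation tests for comparing decoding curves, a synthetic-EEG generator
    with ground-truth burst events, and readers/writers for EDF, BrainVision
    and a native array-plus-JSON container.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
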