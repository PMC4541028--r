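Package: eegfbp
Title: Exploratory Spectral Analysis of Epoched EEG with Functional Boxplots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Depth-based exploratory spectral analysis of epoched
    electroencephalogram (EEG) recordings. Estimates per-epoch spectra by
    boxcar smoothing of the periodogram with the smoothing span selected
    automatically by gamma generalized cross-validation, forms log
    bias-corrected spectral curves, ranks families of curves by band depth
    and modified band depth, and summarizes them with functional boxplots
    (median curve, 50% central region, fences, whole-curve outlier flags).
    Scalp maps of band power are ordered by modified volume depth and
    summarized with surface boxplots. A depth-based rank-sum test compares
    median curves or surfaces between two families, with per-channel
    stationarity screens and Bonferroni correction. A synthetic-data module
    generates autoregressive epoch mixtures, band-concentrated AR(2)
    processes, and two-family curve models so the whole pipeline can be
    exercised and calibrated without any recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
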