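Package: spikedec
Title: Spike Sorting for Microelectrode Array Recordings by Deep Embedded
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing extracellular microelectrode-array (MEA)
    recordings of cultured neurons. Implements robust threshold spike
    detection (median-based noise estimation, 5-sigma threshold), trough
    aligned waveform extraction and normalized-gradient preprocessing, and
    a family of deep-learning spike sorters: a deep autoencoder with k-means
    (DeepAE), Deep Embedded Clustering (DEC), Improved Deep Embedded
    Clustering (IDEC), and an autoencoder-ensemble baseline. Includes a
    ground-truthed synthetic extracellular recording simulator with coupled
    fluorescence calcium traces, Hungarian-matched accuracy scoring, a
    benchmarking harness that compares sorters by relative accuracy
    improvement, and calcium-trace analysis (polynomial bleach correction,
    spike detection, delta-F/F, spike-rate and mutual-information
    synchronicity statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
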