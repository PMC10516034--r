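Package: tricorr
Title: Triple Correlation, Motif-Class Spectra and 4D Shannon Entropy for
    Spike Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes neural network activity recorded as binary spike
    rasters through its triple correlation: contributions from all triplets of
    spikes are accumulated over a bounded window of two spatial and two
    temporal lags into a four-dimensional lag distribution, classified into
    the 169 three-node spatiotemporal configurations and their 14 motif
    classes (spike rate, autocorrelation, synchrony, cross-correlation,
    feedback, divergence, convergence, feedforward, and mixed forms), and
    normalized into a probability distribution whose Shannon entropy (in
    bits) summarizes overall network organization. Spike-rate-matched
    surrogate ensembles provide the chance-level reference for motif-class
    prevalence and entropy, and an epoch/cohort pipeline aggregates
    longitudinal multi-well recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
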