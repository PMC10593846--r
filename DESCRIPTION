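Package: tdehmm
Title: Transient Spectral Network States via Time-Delay Embedded Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes multichannel electrophysiological recordings into a
    small number of transient, spectrally resolved network states. The pipeline
    applies symmetric leakage orthogonalization, time-delay embedding and PCA
    reduction, fits a variational-Bayes Gaussian hidden Markov model on the
    reduced data, and characterises the inferred states temporally (fractional
    occupancy, lifetimes, interval times, event-locked occupancy with a
    two-level GLM and max-statistic permutation inference), spectrally
    (state-weighted multitaper power and coherence, non-negative matrix
    factorization into frequency modes) and spatially (z-scored power maps,
    Gaussian-mixture thresholded coherence networks). A seeded simulator of
    Markov-switching oscillatory network data with an n-back-style event
    schedule provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mclust,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
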