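Package: docm
Title: Dominant Coupling Modes for Multiplex Dynamic Brain Connectivity and Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates time-varying within-frequency phase coupling (imaginary
    phase-locking value) and cross-frequency phase-to-amplitude coupling from
    multichannel band-limited neurophysiological time series, statistically
    selects one dominant coupling mode (DoCM) per region pair and sliding
    window via single-cut surrogate nulls with Bonferroni and
    Benjamini-Hochberg filtering, and derives chronnectomic descriptors
    (comodulograms, flexibility index). The temporal evolution of DoCM label
    sequences is modelled per connection with discrete hidden Markov models
    trained by Baum-Welch, supporting within-study identification of
    individuals, external-cohort matching with learned log-likelihood
    thresholds, differentiability scores, subnetwork analyses, and spectral,
    static-connectome, dynamic-strength and random-edge baselines. Includes a
    synthetic-cohort generator with planted, Markov-switching couplings for
    validation without access to real magnetoencephalography data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
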