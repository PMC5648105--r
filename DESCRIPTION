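Package: connmaps
Title: Reference-Electrode Connectivity Maps for Multi-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Connectivity analysis of multi-channel event-related EEG built
    around reference-electrode connectivity maps: lag-maximized windowed
    cross-correlation between trial-aggregated electrode signals, per-group
    connectivity and dispersion maps, Fisher-score discrimination matrices,
    and reference-relative features (differences and products of a pair's
    connectivity as seen from a third electrode).  Includes epoch ingestion
    from EDF/BDF recordings or plain-text fixture directories, band
    decomposition and artifact rejection, Laplacian-score feature selection
    with a K1/K2 search grid, two-class Gaussian likelihood classification
    under leave-one-out cross-validation, permutation significance, and a
    synthetic two-group ERP cohort generator with planted lagged couplings
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
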