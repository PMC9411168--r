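Package: kinact
Title: Upstream Kinase Activity Inference from Peptide Microarray Kinomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers upstream kinase activity from peptide microarray
    (kinome array) fluorescence data. Reduces per-spot exposure-time
    series to one log2-scale value per peptide per sample, filters
    peptides on curve fit and signal, builds a peptide-to-kinase map
    from homology-score candidate tables, and scores each kinase with
    the Mean Kinase Statistic together with permutation-based
    significance (sample-label permutation) and specificity (peptide
    resampling) scores combined into a Mean Final Score. Activated
    kinases seed an interaction sub-network grown by connectivity
    preference. A companion phosphoproteomics workflow calls
    differential phosphosites from reporter-ion intensities and ranks
    signaling pathways by the number of differential sites catalyzed by
    their member kinases. Includes a synthetic-data generator with
    planted ground truth so the whole pipeline can be exercised and
    calibrated without proprietary instrument software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
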