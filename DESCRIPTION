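Package: mrscreen
Title: Master-Regulator Screening from Probe-Level Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Comparative gene-expression screen for candidate master
    regulators of direct cell reprogramming from Affymetrix-style
    probe-level (PM/MM) microarray data of four cell populations (source,
    source-origin, target and target-stem cells). Provides from-scratch
    implementations of RMA preprocessing (normal+exponential background
    correction, quantile normalization, median-polish probe-set
    summarization) and MAS5-style Present/Marginal/Absent detection calls
    via an exact Wilcoxon signed-rank test on probe-pair discrimination
    scores; a multi-contrast fold-change and detection-call intersection
    screen with transcription-factor filtering and probe-set-to-gene
    collapsing; a synthetic probe-level data generator with planted
    regulators and exhaustive confounder patterns for download-free
    validation; and a pipeline driver with a reproduction harness for the
    deposited GEO arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
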