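Package: dualvfa
Title: Dual-Mode Vertical-Flow Immunoassay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for dual-mode (colorimetric and
    chemiluminescent) multiplexed vertical-flow immunoassays of cardiac
    biomarkers (cTnI, CK-MB, NT-proBNP): sensing-membrane image rendering
    and spot-signal extraction, background-normalised absorption features,
    3-sigma digital quality control, power-law and four-parameter-logistic
    calibration with limit-of-blank/limit-of-detection estimation, a
    cascaded shallow neural-network classification and quantification
    scheme with agreement-based quality assurance, greedy backward feature
    elimination, and a synthetic-data generator that emulates the
    statistical structure of such assays so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
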