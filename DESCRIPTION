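Package: boldvar
Title: BOLD Signal Variability, Complexity, and Brain-Behavior Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing resting-state BOLD signal variability
    (mean square successive difference, MSSD) and complexity (sample entropy)
    at the region-of-interest level, together with the surrounding analysis
    machinery: CSF-reference calibration of the sample-entropy parameters
    (m, r) via the standard error of entropy estimates, weighted global
    efficiency of structural connectomes with anatomical-presence masking and
    head-motion residualization, mean-centering and behavioral partial least
    squares with permutation significance and bootstrap-ratio reliability,
    the supporting univariate statistics (pooled t, chi-square, Pearson r,
    Fisher r-to-z comparison, variance-ratio F), and a synthetic-data
    generator so every stage is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
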