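Package: dnamclock
Title: Building and Applying DNA Methylation Age Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for constructing and applying elastic-net DNA methylation
    age estimators of the skin & blood clock family. Covers reading and
    validating Illumina-style beta-value matrices, calibrated piecewise
    log-linear age transformation, cross-platform CpG preselection,
    cross-validated elastic-net clock training with an in-package coordinate
    descent solver, DNAm age prediction with mean imputation of missing
    probes, epigenetic age-acceleration analysis against a control reference
    regression, nonparametric group comparison, cell-culture population
    doubling bookkeeping, and a synthetic methylation data generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
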