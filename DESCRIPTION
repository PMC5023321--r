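Package: npmap
Title: Normative Modelling with Gaussian Processes and Extreme Value Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for normative modelling of cohort data: per-location Gaussian
    process regression with automatic relevance determination links clinical
    covariates to biological response variables, yielding predictive means and
    variances from which per-subject normative probability maps (Z-score
    deviation maps) are computed under grouped cross-validation. Subject-level
    deviation is summarised by trimmed block-maxima statistics, calibrated with
    extreme value (Gumbel/GEV) distributions, localised with false discovery
    rate control, and related to symptom scores via tail correlations. Includes
    a synthetic cohort generator with family structure and planted outliers,
    and a command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
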