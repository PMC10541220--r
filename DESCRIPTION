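Package: perfrad
Title: Temporal Radiomics for Stress/Rest Myocardial Perfusion CMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for detecting per-territory myocardial
    perfusion defects from time-resolved stress/rest first-pass cardiac MR
    perfusion sequences. Computes first-order and gray-level size zone
    matrix (GLSZM) radiomic features per timestep on coronary-territory
    sub-masks of the left-ventricular myocardium, forms stress-minus-rest
    delta sequences, encodes them as histograms, and classifies the
    resulting per-territory feature vectors with a balanced random forest
    under nested grouped cross-validation with specificity-matched
    probability thresholding. Includes a synthetic first-pass perfusion
    phantom generator with known territory-level disease labels so the
    whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
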