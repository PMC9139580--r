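Package: ctpcore
Title: End-to-End Classification of Ischemic Core Volume from CT Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying end-to-end deep learning on 2D+t CT perfusion
    (CTP) data in acute ischemic stroke. Provides a seeded digital CTP phantom
    with exact tracer-kinetic ground truth (CBF/CBV/MTT maps and ischemic core
    volumes), conventional indicator-dilution analysis (AIF selection,
    truncated-SVD deconvolution, CBV-threshold core volumetry, median
    dichotomization), preprocessing of raw stacks onto a standardized grid
    (temporal interpolation, in-plane resampling, rigid co-registration), a
    spatiotemporal convolutional network that classifies patients into small
    versus large core directly from slice-reduced CTP stacks, and a
    cross-validation harness with early stopping, fold ensembling, ablation
    runs and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
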