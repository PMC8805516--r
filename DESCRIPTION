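Package: aneuscan
Title: Candidate-Based Cerebral Aneurysm Detection on TOF-MRA-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end candidate-based detection of cerebral aneurysms on
    time-of-flight magnetic resonance angiography (TOF-MRA) volumes:
    isotropic resampling and Nyul-Udupa intensity standardization,
    three-sigma artery extraction, multiscale Hessian selective-enhancement
    filtering for candidate generation, 15-view maximum-intensity-projection
    panels, planar (2D), stereoscopic (3D) and fused multidimensional (MD)
    convolutional classifiers with squeeze-and-excitation residual blocks,
    vote-based region aggregation, and free-response ROC (FROC) evaluation.
    Includes a seeded synthetic vascular-phantom generator with per-aneurysm
    ground truth so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    xgboost,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
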