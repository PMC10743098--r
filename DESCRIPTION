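Package: jacreg
Title: Direct Regression of Lung Volume-Change Maps from CT with a 3D Residual Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates high-resolution maps of local lung volume change (the
    Jacobian determinant of the inflation deformation) directly from single or
    paired chest CT volumes using a 3D multiscale residual regression network.
    Includes the full preprocessing chain (anti-alias resampling to isotropic
    spacing, union-bounding-box cropping, masking, HU clamping and rescaling),
    a composite mean-absolute-error and structural-similarity training loss,
    a 2x2 multifactorial training harness (single versus paired input, FRC
    versus TLC output space), a synthetic paired-inflation phantom simulator
    with analytic ground-truth Jacobians, and a local/regional/global
    evaluation suite with parametric response mapping and agreement summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
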