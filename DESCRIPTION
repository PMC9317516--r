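Package: spineacc
Title: Accuracy Measurement and Non-Inferiority Analysis for Pedicle Screw
    Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the three-dimensional accuracy of pedicle
    screw placement from CT imaging and for the statistical analysis of
    split-spine non-inferiority trials comparing navigation techniques.
    Provides synthetic vertebra-like CT phantoms with screws planted at
    controlled deviations, Hounsfield-threshold screw segmentation,
    trimmed iterative-closest-point rigid registration, analytic
    least-squares cylinder fitting, entry-point and angular deviation
    metrics, pedicle breach-margin simulation, block-balanced side
    randomization, and one-sample t based non-inferiority inference with
    sample-size and simulated-power calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
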