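Package: buriti
Title: Confidence-Map Detection of Individual Palm Trees in Aerial RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and geolocates individual Mauritia flexuosa (buriti) palm
    trees in aerial RGB orthomosaics by regressing per-pixel confidence maps.
    Ground truth is rendered as Gaussian kernels centred on point annotations
    with a stage-wise sigma schedule (broad first, sharp last); a truncated
    VGG backbone with a pyramid pooling module feeds a multi-stage refinement
    module trained with per-stage squared-error loss; tree centres are read
    off the final map as strict 4-neighbour local maxima above a confidence
    threshold with a minimum peak separation.  Includes a synthetic-scene
    generator with exact centre ground truth, orthomosaic tiling and
    region-based splitting, point-matching evaluation (MAE, precision,
    recall, F1) and a hyperparameter sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    tiff,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
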