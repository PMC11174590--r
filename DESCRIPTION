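Package: canopywater
Title: Leaf Moisture Estimation from Multispectral Canopy Imagery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Estimates crop leaf moisture content (percent of fresh mass)
    from multiband canopy imagery. Implements per-plot mean-reflectance
    extraction from region-of-interest polygons, ten classical vegetation
    indices, gray-level co-occurrence matrix (GLCM) texture features over
    sliding windows, an exhaustive search over pairwise texture indices
    (ratio, difference, sum, normalized-difference and reciprocal forms),
    correlation-based significance screening of candidate predictors, and
    three regression models (extreme learning machine, gradient-boosted
    trees, and a Levenberg-Marquardt-trained backpropagation network)
    compared by R-squared, RMSE and mean relative error. A synthetic scene
    generator emulating a mulch-by-irrigation split-plot soybean trial makes
    every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    mgcv,
    MASS,
    xgboost,
    Rcpp,
    EBImage,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
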