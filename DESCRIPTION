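Package: socscape
Title: Spatially Explicit Forest Soil Organic Carbon Mapping with
    Quantile Regression Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for digital soil mapping of forest soil organic carbon
    (SOC) stocks in mountainous terrain. Builds scorpan covariate stacks
    from a digital elevation model (slope, topographic position and
    wetness indices, wind exposure, walking-cost and forest-edge-distance
    surfaces), fits quantile regression forests that retain the full
    conditional SOC distribution per prediction cell, evaluates models
    with cluster-aware (leave-location-out) spatial cross-validation,
    maps model and sampling-design uncertainty and combined percent
    error, screens predictions with the dissimilarity-index Area of
    Applicability, diagnoses residual spatial autocorrelation with
    permutation-envelope semivariograms, aggregates fine-resolution
    predictions for comparison against coarse reference products, and
    totals national SOC stocks with standard errors. Includes a fully
    synthetic landscape generator (spectral DEM, Gaussian random fields,
    clustered plot designs) so the whole pipeline is testable end to end
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger
Config/testthat/edition: 3
RoxygenNote: 7.3.3
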