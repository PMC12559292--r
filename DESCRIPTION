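Package: carbonscape
Title: Forest Carbon Storage Estimation from Plot Inventories and
    Paired-Resolution Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for regional forest carbon accounting in
    semi-arid landscapes: allometric plot-level carbon density from stem,
    shrub and herb-quadrat inventories; vegetation-index regression of
    carbon density against multiband reflectance at 10 m and 30 m
    resolution (random forest, decision tree, multiple linear regression);
    a cross-resolution reference-transfer scheme that aggregates
    fine-resolution per-species predictions to the coarse grid and uses
    them as training targets; discrepancy mapping between estimates;
    Gaussian maximum-likelihood land-cover classification with confusion
    statistics; storage aggregation, composition and temporal change; and
    geodetector factor and interaction analysis of stratified spatial
    heterogeneity. A seeded synthetic-scene generator with exact 3x3 grid
    nesting and known ground truth makes every stage testable without
    satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    rpart,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
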