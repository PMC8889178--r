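Package: ensdm
Title: Ensemble Ecological Niche Modelling with Range-Change and
    Fragmentation Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits ensembles of presence/absence species distribution
    models (GLM, GBM, GAM, CTA, ANN, SRE, FDA, MARS, RF, MAXENT) to
    gridded environmental layers, gates candidate models by ROC score,
    combines them into ROC-weighted mean ensembles with aggregated
    permutation variable importance, and projects habitat suitability
    under current and future climate scenarios.  Downstream tools build
    majority-vote consensus binary maps, classify per-pixel range
    transitions (never/always/lost/gained), compute range change under
    full-dispersal and no-dispersal assumptions, and calculate landscape
    fragmentation metrics (patch counts and areas, splitting index,
    aggregation index).  Includes collinearity filtering by variance
    inflation factor, plain-text (ESRI ASCII) raster input/output, and a
    seeded synthetic-landscape generator for end-to-end validation
    against known niche structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    mgcv,
    nnet,
    rpart,
    randomForest,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
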