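Package: helixclass
Title: Classification of DNA Mutational Hotspots from Helical-Parameter
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying bulky-adduct mutational hotspot versus
    nonhotspot DNA duplexes from molecular-dynamics-derived helical
    base-pair parameter time series. Reads and writes Canal-style
    per-parameter series files, assembles trajectory bundles from a sample
    manifest, converts trajectories into per-simulation feature matrices
    (equilibration-window exclusion, terminus trimming, temporal
    aggregation over a 17-parameter schema), benchmarks a panel of 15
    classifiers, trains and grid-search-optimizes a random-forest model,
    deploys it to unseen gene contexts, consolidates three
    feature-selection rankings into a single score, and compares regional
    G/C content between hotspot and nonhotspot sequences. A
    synthetic-trajectory generator with planted mean-shift effects and
    AR(1) noise makes every stage testable without molecular-dynamics
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    glmnet,
    e1071,
    kernlab,
    xgboost,
    rpart,
    nnet,
    MASS,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
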