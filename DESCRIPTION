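Package: actiphen
Title: Actigraphy Feature Engineering and Cross-Model Shapley Attribution for Digital Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving zero-crossing-method (ZCM) activity series from raw
    wrist-accelerometer recordings, extracting a 96-feature registry of circadian,
    smoothed-boundary, nocturnal peak-shape, fragmentation and Morlet-wavelet
    structure features, selecting low-correlation feature subsets by Welch screening
    and maximal-clique enumeration, training logistic-regression, random-forest and
    gradient-boosting classifiers under stratified 10-fold cross-validation against
    a 3-feature baseline, and aggregating Shapley attributions across above-baseline
    models into direction-annotated importance rankings. A synthetic cohort
    generator produces labeled raw recordings with injectable group effects so
    every pipeline stage is testable without access to a clinical cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    igraph,
    randomForest,
    xgboost,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
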