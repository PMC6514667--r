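Package: voxconn
Title: Predicting Brain-Region Connectivity from Voxel-Level Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating classifiers that predict the
    anatomical connectivity between brain regions from voxel-level in-situ
    hybridization gene-expression grids, in the style of the Allen Mouse
    Brain Atlas.  The package covers the full workflow: readers and writers
    for raw expression volumes, NRRD projection volumes, structural
    annotation vectors and hierarchical structure graphs; median-then-max
    aggregation of tracer-injection projection data into per-pair
    connectivity values with threshold-based class labels; construction of
    normalized Source-Target expression vector datasets with stratified
    train/validation/test splits; and a seeded multilayer-perceptron
    classifier with Nadam optimisation, dropout, and full evaluation
    reports (confusion matrices, precision/recall/F1, ROC/AUC).  A
    synthetic-atlas generator with a planted, tunable
    expression-connectivity signal makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
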