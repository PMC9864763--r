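Package: sirtscreen
Title: QSAR Model Building and Virtual Screening for Sirtuin-2 Inhibitor
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates heterogeneous structure-activity records (IC50 and
    percent-inhibition measurements across sirtuin isoforms) into
    regression and classification datasets, computes molecular
    fingerprints (ECFP4/ECFP6/MACCS) and 2D descriptors with a
    train-only feature-selection chain, trains potency and
    isoform-selectivity models over five algorithm families with
    sequential model-based hyperparameter search, and validates them
    with a full external-validation battery (QF2 metrics, rm2 metrics,
    Lin's concordance correlation, Golbraikh-Tropsha criteria, balanced
    accuracy, Matthews correlation, ROC enrichment on property-matched
    decoy sets). Prediction confidence is reported through
    leverage-based applicability domains, probability confidence zones
    and atom-contribution similarity maps; end-user virtual-screening
    and per-compound analysis workflows are included. A synthetic
    structure-activity generator with a planted substructure signal
    makes the whole suite testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    MASS,
    e1071,
    igraph,
    jsonlite,
    lhs,
    pROC,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
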