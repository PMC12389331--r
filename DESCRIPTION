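Package: ddipredict
Title: Similarity-Based Prediction of Drug-Drug Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A guilt-by-association pipeline for predicting drug-drug
    interactions (DDIs) from drug feature similarity. Six per-feature
    drug-drug similarity matrices (chemical structure, merged
    targets/enzymes/carriers/transporters, adverse drug events, pathways,
    interactome proximity of protein targets, and interaction profile
    fingerprints) are built with the Tanimoto index, propagated through
    the known-interaction matrix, and integrated into one unified score
    per drug pair by principal component analysis. Performance is
    estimated by masked 10-fold cross-validation (AUROC, Youden operating
    point) and novel interactions are called above the third quartile of
    known-interaction scores, then classified as pharmacokinetic,
    pharmacodynamic or adverse-event effects and summarised as per-drug
    discovery rates and group tables. A cluster-structured synthetic
    drug-universe generator makes the whole pipeline testable without
    access to licensed drug databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
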