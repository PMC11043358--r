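Package: pharmsense
Title: Drug-Response Measures and Sensitivity Prediction for Pharmacogenomic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the choice of drug-response measure
    (ln-IC50, AUC, normalized AUC, drug relevance score, and their per-drug
    z-scores) shapes drug-sensitivity prediction. Implements dose-response
    curve summarisation from per-dosage viability data, per-drug z-score
    normalization, the pairwise cell-line profile-correlation diagnostic,
    multicollinearity-aware drug-specific gene selection with a
    cross-validated threshold sweep, baseline prediction models (per-drug
    mean, single-drug regressors, bimodal nearest-neighbour, feed-forward
    network) with a zero-filled-omics ablation, ranking metrics
    (Precision at k, NDCG at k), cell-line-disjoint cross-validation, and a
    synthetic pharmacogenomic screen generator that reproduces the
    statistical structure of large public screens without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
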