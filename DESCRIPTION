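Package: mvmrmr
Title: Multi-View Minimum-Redundancy Maximum-Relevance Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for multi-omics classification problems in
    which several feature matrices ("views", e.g. copy-number, methylation
    and expression profiles) are measured on the same samples. Implements
    the greedy minimum-redundancy maximum-relevance (MRMR) criterion for a
    single view and its multi-view extension, in which selection steps are
    allocated to views by sampling from a view-importance distribution
    while the redundancy penalty is computed against features already
    selected from every view. A two-stage gated filter framework combines
    trainable view-specific filters (e.g. an L1-penalised embedded filter)
    with a single- or multi-view second-stage selector. Ships a synthetic
    multi-view data generator with planted relevant, redundant and
    complementary features, and a repeated stratified cross-validation
    harness that compares single-view, concatenation, per-view-union,
    multi-view and ensemble modelling strategies by AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ranger,
    xgboost,
    optparse
Config/testthat/edition: 3
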