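Package: sllesc2
Title: Feature Gene Selection by Supervised Locally Linear Embedding and
    Spearman Correlation Redundancy Filtering
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects small panels of discriminative, non-redundant feature
    genes from two-class gene-expression matrices. A supervised variant of
    locally linear embedding (class-label-inflated distances) maps samples
    to a low-dimensional space; genes are ranked by their rank-correlation
    association with the embedding components weighted by PCA explained
    variance; a greedy Spearman-correlation filter removes coexpressed
    (redundant) genes above a threshold. Includes imbalanced-classification
    metrics (G-mean, AUC), stratified cross-validation with selection
    nested inside folds, a correlation-threshold sweep, and a synthetic
    two-class expression generator with planted coexpression blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
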