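Package: exprattn
Title: Attention-Based Interpretable Classification of Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of high-dimensional expression profiles
    (samples by genes, or samples by gene sets) with a feature-level
    self-attention network that yields a per-sample, per-feature importance
    score alongside the class probability. Includes count preprocessing
    (zero-feature filtering, median-of-ratios size factors, gene-set
    aggregation from GMT collections), post-hoc interpretation of the
    importance matrix (non-negative matrix factorisation with
    discriminative-factor selection, PCA ordination, clinical-stage
    association models), baseline classifiers, a negative-binomial synthetic
    cohort generator with planted signal, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    DESeq2
Config/testthat/edition: 3
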