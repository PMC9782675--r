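Package: txclust
Title: Consensus-Clustering Phenotype Discovery for Kidney Transplant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised phenotype discovery for kidney-transplant registry
    cohorts with mixed-type recipient, donor and transplant variables.
    Provides a synthetic-registry generator with planted cluster structure,
    inclusion filtering and chained-equation imputation, Gower dissimilarity,
    subsampling-based consensus clustering with stability diagnostics
    (consensus CDF, delta area, proportion of ambiguously clustered pairs,
    within-cluster consensus scores), standardized-mean-difference cluster
    characterization, and cluster-wise comparison of post-transplant outcomes
    via Kaplan-Meier curves, log-rank, chi-squared and one-way ANOVA tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    survival,
    nnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
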