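Package: stressnet
Title: Multi-Condition Co-Expression Networks via Condition-Adaptive Fused
    Graphical Lasso and Cross-Species Orthogroup Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of condition-specific gene co-expression
    networks under a Gaussian graphical model with lasso and sequential
    condition-adaptive fused penalties (ADMM), preceded by the standard
    RNA-seq preprocessing chain (CPM filtering, log transformation,
    group-aware smoothed quantile normalization, empirical-Bayes covariate
    adjustment, standardization).  Per-species condition-union networks are
    projected into hierarchical orthogroup (HOG) space for cross-species
    comparison, edges are classified by a clade-conservation rule, and gene
    sets are tested for GO-term overrepresentation with exact
    hypergeometric tests.  A synthetic-data generator with known precision
    matrices and planted conserved orthogroup edges makes every stage
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
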