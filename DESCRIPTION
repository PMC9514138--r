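Package: scnet
Title: Structural Covariance Networks from Regional Cortical Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level structural covariance network analysis of regional
    cortical thickness. Networks are binary undirected graphs whose edges are
    the nonzero partial correlations selected by an L1-penalized (graphical
    lasso) sparse inverse covariance estimate, with the regularization
    parameter chosen by cross-validation. Provides segregation and integration
    graph metrics (mean local efficiency, global efficiency, and modularity
    quantified as the mean participation coefficient over a Louvain
    partition), nonparametric permutation tests of group differences in these
    metrics across two timepoints with Benjamini-Hochberg false discovery
    rate control, median-split group formation with an ANOVA covariate
    screen, quality screening of thickness tables, and a synthetic
    longitudinal cohort generator with block-structured covariance for
    testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
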