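Package: prede
Title: Partial Reference-Based Deconvolution of Bulk Expression Mixtures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deconvolution of bulk gene expression mixtures when reference
    profiles are available for only a subset of the constituent cell types.
    Estimates the proportions of all cell types together with the expression
    profiles of the unknown ones by alternating constrained optimization of a
    partial-reference non-negative matrix factorization: a quadratic program
    per sample for proportions (non-negative, column sum at most one) and
    non-negative least squares per gene for the unknown basis. The total
    number of cell types is chosen by minimizing the small-sample-corrected
    Akaike information criterion over a candidate grid. Includes a mixture
    simulator (Dirichlet proportions, mean-proportional Gaussian noise, rare
    populations, similarity-controlled basis profiles, grouped
    cancer/immune/normal designs), accuracy metrics (component matching by
    optimal assignment, mean absolute error, Pearson correlation, Shannon
    heterogeneity, Bray-Curtis dissimilarity), delimited-matrix input/output
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
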