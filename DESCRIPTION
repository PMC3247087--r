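Package: qdadetect
Title: Detection of Weak Marginal, Strong Bivariate Interactions with
    Quadratic Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies pairs of features whose individual class-conditional
    distributions overlap but whose joint distribution separates two
    phenotype classes, in small-sample high-dimensional expression data.
    Provides a from-scratch binary quadratic discriminant analysis (QDA)
    classifier with stratified cross-validated error estimation, a blockwise
    exhaustive pair-search procedure that ranks block matchings by QDA error
    and refines top matchings into pairwise error heat matrices, synthetic
    generators for four planted interaction patterns (linear, XOR, circular,
    V-shaped), a simulation bench for the peaking phenomenon including the
    signal-versus-noise overlap experiment, and the TSP and CorScor pair
    association scores for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
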