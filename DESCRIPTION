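Package: pairtree
Title: Ensemble Rank-Based Trees for Single-Sample Classification of
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision trees whose every split compares the expression of two
    genes within the same sample (x_i <= x_j), so that classification depends
    only on within-sample ranks and is invariant to monotone, per-sample
    measurement distortions across platforms.  Single trees generalise the
    top-scoring-pair classifier; they are ensembled by a class-balanced
    random forest with out-of-bag error estimation and by gradient boosting
    under the LogitBoost cost, with one-against-all handling of multi-class
    outcomes.  Includes extraction of compact if-then rules from forest
    terminal nodes, permutation importance for gene pairs, a two-stage
    dimension-reduction procedure (gene selection, then gene-pair selection),
    a replicated benchmarking and parameter-sweep harness, and a synthetic
    data generator with planted pairwise rank structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
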