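Package: fimbic
Title: Coherent-Column Biclustering of Expression Matrices via Maximal
    Frequent Itemset Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustively enumerates coherent-column biclusters from a gene
    expression matrix by sliding-window discretization of each condition and
    maximal frequent itemset mining, scores each bicluster with an empirical
    permutation p-value on the average pairwise Pearson correlation of its
    rows, merges redundant biclusters that share a condition set, and builds
    weighted gene set networks in which nodes are maximal gene sets with
    identical bicluster membership.  Includes a synthetic-data generator with
    implanted ground-truth biclusters, recovery scoring, tidy accessors and
    GraphML export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
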