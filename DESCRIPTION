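Package: ceclc
Title: Joint Association Testing of Multiple Phenotypes via Clustered
    Linear Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tests the association between a genetic variant and multiple
    correlated phenotypes. Per-trait score statistics are combined through
    the clustering linear combination (CLC) family of chi-square tests:
    phenotypes are clustered hierarchically on their sample correlation
    matrix, a quadratic-form statistic is computed for every possible
    number of clusters, and the resulting p-values are aggregated either
    by the Cauchy combination (the computationally efficient ceCLC test,
    which has a closed-form p-value) or by the minimum p-value with a
    Monte-Carlo null (the original CLC test). Includes the O'Brien and
    omnibus chi-square tests as special cases, a factor-model phenotype
    simulator with liability-threshold binary traits, and drivers for
    type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
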