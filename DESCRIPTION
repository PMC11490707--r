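Package: traitnets
Title: Trait Co-Occurrence Networks for Marine Community Resilience
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds trait co-occurrence networks for modern and fossil marine
    communities. Categorical species traits are expanded to binary trait
    values, combined with site-by-species abundance or presence data into
    community-weighted means (or used directly when no site structure
    exists), correlated pairwise, thresholded, and assembled into an
    undirected trait network. Provides the resilience-oriented network
    metrics (modularity with module detection, edge density, Freeman degree
    centralization, node degree and keystone-trait ranking), significance
    assessment against Erdos-Renyi G(n,m) null ensembles via permutation
    tests, bootstrap network ensembles with two-group comparisons
    (confidence intervals, Welch t, Mann-Whitney U), a synthetic community
    generator with planted life-history strategy blocks for validation, and
    an end-to-end command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
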