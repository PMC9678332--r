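Package: echonet
Title: Quantifying Topic- and Attitude-Based Echo Chambers in Social Media Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying echo chambers in social-media discourse from
    tabular interaction corpora (users and tweets). Builds undirected
    information-representation networks over original posts and directed user
    communication-flow networks from retweet and comment relations, measures
    homophily with categorical mixing matrices and Newman's assortativity
    coefficient, computes Burt's ego-network structural-hole indices (effective
    size, efficiency, constraint, hierarchy), classifies users by a behavior
    taxonomy and stakeholder keyword lexicon, detects opinion leaders and
    structural-hole spanners, codes users as echoers or bridgers, and tests
    role associations with support/confidence and Pearson chi-square
    statistics. Includes a seeded synthetic-corpus generator with planted,
    analytically calibrated homophily for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
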