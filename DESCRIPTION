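Package: crthte
Title: Simulation of Subgroup and Treatment-Effect-Heterogeneity Analyses
    in Cluster-Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the operating characteristics of
    heterogeneity-of-treatment-effect (HTE) analyses in cluster-randomized
    trials when an individual-level subgroup variable (e.g., self-reported
    race) must be aggregated to the cluster level. Generates individual-level
    trial data under a linear probability model with configurable subgroup
    effects and interactions, assigns clusters to arms by constrained
    randomization stratified by region and balanced on urban/rural status,
    aggregates subgroup variables to cluster-level proportions or threshold
    indicators, fits a grid of individual- and cluster-level linear models
    with cluster-robust sandwich variance and a small-sample correction, and
    summarizes Monte-Carlo type-I error, power, and bias.
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
    parallel,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
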