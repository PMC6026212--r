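Package: crankr
Title: Prioritization of Network Communities by Structural Robustness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks communities detected in a network so that the most
    promising candidates for downstream follow-up appear first. Four
    structural prioritization metrics (likelihood, density, boundary,
    allegiance) are each evaluated on the observed network and under an
    analytic degree-preserving edge-rewiring perturbation, combined into
    robustness scores, and aggregated into a single prioritization by an
    unsupervised iterative Bayes-factor rank aggregation. Includes an
    affiliation-model community detector, a crisp-partition adapter for
    arbitrary detection methods, modularity/conductance/random ranking
    baselines, and a stochastic block model benchmark with gold-standard
    evaluation by Spearman rank correlation.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
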