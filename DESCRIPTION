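Package: hdmrnet
Title: Signaling Network Inference with Random-Sampling HDMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers biological network structure from multivariate
    single-cell-style measurements using Random Sampling High Dimensional
    Model Representation (RS-HDMR). Fits hierarchical expansions of
    data-adaptive orthonormal polynomial component functions per output
    node, prunes candidate terms by F-test model reduction, decomposes
    output variance into per-component sensitivity indices (with
    covariance contributions under correlated inputs), aggregates total
    sensitivities across experimental conditions into a thresholded
    directed network, and reuses the fitted expansions as forward
    predictors of unmeasured nodes and as inverse classifiers of
    perturbation conditions. A synthetic benchmark module generates
    ground-truth data with known component functions, indirect chains
    through measured intermediates, and perturbation pairs, together
    with analytic sensitivity oracles.
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
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
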