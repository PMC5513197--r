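Package: exposelect
Title: Simulation Benchmark of Variable Selectors for Exposome Interaction Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark statistical variable-selection methods for
    detecting two-way exposure interactions in exposome-wide association
    settings. Provides a calibrated generator of realistic exposome
    correlation structures (237 correlated exposures in families, with
    high- and low-correlation blocks), outcome scenarios with zero, one or
    two pairwise interactions, six selectors (two-step EWAS, the
    deletion/substitution/addition search with and without interaction
    terms, a screen-tree-search pipeline, the lasso, and a strong-hierarchy
    group-lasso interaction model, plus boosted regression trees with
    backward variable elimination), and thirteen performance measures
    including correlation-aware sensitivity and false-discovery variants.
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
    glmnet,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
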