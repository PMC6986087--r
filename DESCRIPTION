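Package: costsel
Title: Cost-Constrained Feature Selection for Binary Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection under a hard additive cost budget for binary
    classification. Implements benefit-cost-ratio greedy forward selection
    with trade-off adaptations, a genetic algorithm with a graded
    constraint-violation fitness, a cost-preserving genetic algorithm whose
    initialisation, crossover and mutation operators never leave the budget,
    and budget-constrained filter baselines. Includes a synthetic simulation
    framework (multivariate-normal and logistic generative models, several
    cost regimes, heavy-tailed features) and an evaluation harness computing
    test AUC and precision/recall of relevant-feature recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
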