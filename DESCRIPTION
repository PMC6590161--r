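Package: treatthresh
Title: Treatment Thresholds from Expected-Utility Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form treatment thresholds for clinical decision-making
    under expected utility theory: the classic threshold probability of
    disease above which treatment is warranted, its evidence-based
    parameterization in terms of relative risk reduction, treatment harm and
    an explicit preference weight, and the outcome-risk threshold that
    applies when the morbid outcome is itself part of the disease definition
    (avoiding double counting by taking the diagnosis as certain). Includes
    conversions between effect metrics (RRR, ARR, NNT, NNH, odds ratios), a
    deterministic bisection solver and a Monte Carlo simulator that locate
    thresholds directly on the decision tree as independent checks of the
    closed forms, one-way sensitivity sweeps over harm risk and preference
    weights, and YAML/JSON scenario configuration with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
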