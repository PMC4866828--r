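Package: savouR
Title: Reward-Prediction-Error Boosted Anticipation Models of Information Seeking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Valuation of reward-predictive cues under the utility of
    anticipation (savouring and dread) with exponential temporal discounting,
    where the weight on anticipation is boosted by the reward prediction error
    evoked by the cue. Provides closed-form cue values, self-consistent
    fixed-point solutions for the boosted value, forward predictions for the
    macaque information-choice task and generalized pigeon observing tasks
    (including preference phase diagrams), a trial-by-trial learning model of
    human advance-information choice with a six-model comparison zoo,
    synthetic-experiment generators with known ground truth, and hierarchical
    Bayesian random-effects fitting via Laplace-approximate EM with integrated
    BIC model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
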