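Package: prlearn
Title: Probabilistic Reversal Learning Simulation, Reinforcement-Learning
    Modelling and Socioeconomic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reward and punishment learning with the
    probabilistic reversal learning (PRL) task. Simulates the task
    (probabilistic win/loss feedback, contingency reversals after runs of
    consecutive correct choices), implements a three-parameter
    reinforcement-learning model with separate learning rates for positive
    and negative prediction errors and a softmax choice rule, estimates
    the parameters per participant by hierarchical Bayesian MCMC with
    partial pooling (with a non-hierarchical maximum a posteriori fit as a
    cross-check), and provides the statistical layer used in studies of
    socioeconomic adversity and learning: standardized multiple
    regression with variance inflation factors, Pearson correlations,
    one-sample t tests with Cohen's d, and Benjamini-Hochberg false
    discovery rate adjustment. A synthetic-cohort generator produces
    participants with a known hardship/income correlation structure and
    known ground-truth learning parameters for end-to-end parameter
    recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
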