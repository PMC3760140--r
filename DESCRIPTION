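Package: twostepr
Title: Simulation and Multilevel Analysis of the Two-Step Reinforcement-Learning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models and trial-by-trial analysis tools for the
    two-stage sequential decision ("two-step") task used to dissociate
    model-based from model-free reinforcement learning. Provides the task
    environment (70/30 transition structure, Gaussian random-walk reward
    probabilities with reflecting bounds), hybrid SARSA(lambda)/model-based
    softmax agents and population simulators with covariate-linked strategy
    differences, factorial stay/switch encoding of trial sequences,
    per-subject and multilevel (random-slopes) logistic regression with Wald
    tests and linear contrasts, a deviance-based task-engagement score with
    odd/even cross-fitting, and an end-to-end analysis pipeline producing
    stay-probability summaries, moderation models, subgroup re-analyses and
    engagement-interaction contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
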