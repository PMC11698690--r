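Package: stakerl
Title: Stakes-Modulated Two-Step Task Simulation and Dual-System
    Reinforcement-Learning Model Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a stakes-modulated two-step decision task with
    deterministic spaceship-to-planet transitions and drifting planet
    payoffs, fits a dual-system (model-based/model-free) reinforcement
    learning model with stake-conditional mixing weights by maximum a
    posteriori estimation with empirical priors and random restarts, fits
    a risk-sensitive mean-variance utility model with a real-valued
    genetic algorithm, generates synthetic two-group cohorts with known
    ground-truth parameters, and runs the group-level statistics (mixed
    stakes-by-group ANOVA, rank tests, Spearman correlations with
    Bonferroni correction, Fisher z comparison of correlations, and
    split-half reliability of refitted parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    withr,
    ggplot2,
    stats,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
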