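Package: ipdstrat
Title: Strategy Inference and Cooperation Analysis for Iterated Prisoner's
    Dilemma Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing iterated Prisoner's Dilemma experiments in
    which participants play a fixed-horizon game against a scripted
    tit-for-two-tats computer opponent. Provides a catalogue of
    finite-automaton strategies (tit-for-tat variants, Grim triggers, always
    cooperate/defect), a game engine with payoff and emotional-feedback
    bookkeeping, psychometric scoring for a 40-item psychopathy inventory
    with inconsistency-based exclusion, behavioural cooperation metrics,
    regression model selection by repeated k-fold cross-validation
    (Gaussian, binomial and beta-binomial families), and per-participant
    maximum-likelihood strategy frequency estimation under a tremble
    (implementation error) model with bootstrap standard errors. A
    synthetic-cohort generator reproduces the statistical structure the
    analysis assumes so the full pipeline runs end to end without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    glmmTMB,
    knitr,
    rmarkdown
Config/testthat/edition: 3
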