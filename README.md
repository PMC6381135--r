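# ipdstrat

Strategy inference and cooperation analysis for fixed-horizon iterated
Prisoner's Dilemma experiments with a scripted opponent.

## The problem

A common behavioural-economics design has participants play 30 rounds of a
Prisoner's Dilemma (cooperate = keep the standard price, defect = undercut
with a sale price; payoffs 40 > 30 > 20 > 10 in the usual T > R > P > S
ordering) against a computer programmed to play tit-for-two-tats and to
defect in the last two rounds, with emotional facial feedback after each
decision (a 2x2 design of happy-after-cooperation and sad-after-defection)
and a deception factor (told human vs told computer opponent). Participants
then complete a 40-item psychopathy inventory (fearless dominance,
self-centred impulsivity, coldheartedness), a 16-item narcissism inventory,
and an inconsistency screen used for exclusion.

`ipdstrat` is for researchers analysing that kind of data end to end:
behavioural dependent variables and their regressions on traits and design
factors, and — the core — estimating *which strategy each participant was
playing* from their round-by-round choices.

## The model

Strategies are deterministic automata (always-defect ALLD, Grim triggers,
tit-for-tat variants TF2T/TF3T/2TF2T, ...). A player following strategy *s*
executes its prescription each round with probability β and the opposite
action with probability 1 − β (a "tremble"), where β = 1/(1 + e^(−1/γ))
and γ is the implementation-error scale. With m<sub>is</sub> mismatches
between participant *i*'s choices and *s*'s prescriptions along the
realised history over T rounds, the cohort strategy frequencies φ solve
the strategy frequency estimation (SFEM) problem

max<sub>φ, γ</sub> Σ<sub>i</sub> log Σ<sub>s</sub> φ<sub>s</sub> β^(T − m<sub>is</sub>) (1 − β)^m<sub>is</sub>,

fitted by EM with bootstrap standard errors over participants.
Per-participant fits (`fit_subject`), a subject-averaging estimator, and
trait–strategy correlations are also provided; see the methods vignette
(`vignettes/strategy-inference.Rmd`) for the estimator discussion and the
design's identifiability limits.

## Worked example

```r
library(ipdstrat)

# a strategy prescribes an action for any realised history
grim <- build_strategy_set("Grim")[[1]]
prescribe(grim, joint_history(own = c("C","C","C"), opp = c("C","D","C")))
#> [1] "D"

# play a session against the scripted tit-for-two-tats computer
sess <- play_session(function(h) prescribe(grim, h))
table(sess$computer_action)   # defects only in the two endgame rounds
#>  C  D
#> 28  2

# full pipeline on a synthetic cohort at the design's defaults:
# 206 recruited, inconsistency screening, metrics, model selection,
# regressions, strategy inference
run <- run_pipeline(run_config(cohort = cohort_spec(n_participants = 206),
                               seed = 1, bootstrap_B = 1000), quiet = TRUE)
run$strategy$estimate
#> Cohort strategy frequencies (n = 192, estimator = sfem), gamma = 0.92 (0.03)
#>  strategy frequency     se stars
#>      TF3T      0.19 (0.06)   ***
#>     2TF2T      0.19 (0.06)   ***
#>      Grim      0.03 (0.02)
#>      ALLD      0.59 (0.04)   ***
```

Reading the output: after the inconsistency screen removes high scorers
(206 → 192 here), each retained participant's 30 choices are compared with
each catalogued strategy's prescriptions; the table is the estimated share
of the cohort playing each strategy, with bootstrapped standard errors and
stars for difference from zero. `gamma = 0.92` is the fitted
implementation-error scale — the generating cohort used γ = 0.88
(β ≈ 0.76), i.e. participants executed their strategy in roughly three
quarters of rounds, and a majority are best described as always-defect.
The confounded lenient strategies (TF3T/2TF2T) carry visibly larger
standard errors; the vignette explains why the 30-round design cannot
separate them.

The same `run` object carries the behavioural metrics and regressions:
`run$correlations` (cooperation, CaC and traits), `run$cv` (repeated
5-fold cross-validation over Gaussian, logistic and beta-binomial
families), `run$regressions` and `run$interactions`.

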