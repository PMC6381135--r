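---
title: "Strategy inference and cooperation analysis for a fixed-horizon Prisoner's Dilemma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strategy inference and cooperation analysis for a fixed-horizon Prisoner's Dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ipdstrat` analyses a particular class of behavioural experiment: an
iterated Prisoner's Dilemma in which each participant plays a fixed number
of rounds (30 by default) against a scripted computer opponent, receives
payoff and emotional-feedback information after every round, and completes
psychometric questionnaires afterwards. The package provides the game
engine, the psychometric scoring, the behavioural dependent variables and
regressions, and — its analytical core — maximum-likelihood estimation of
the behavioural strategies participants used, under an implementation-error
("tremble") model. A synthetic-cohort generator reproduces the statistical
structure the analysis assumes, so every stage is testable without
participant data.

## The game and the scripted opponent

Actions are cooperate (`C`) or defect (`D`); in the cover story these are a
shop's standard price and sale price, and payoffs are percentage profits in
the standard T > R > P > S ordering (40 > 30 > 20 > 10). The computer plays
tit-for-two-tats: it cooperates until the participant defects twice in a
row, then defects until the participant cooperates once. In the final two
rounds it defects unconditionally, imitating human endgame behaviour.
Feedback after each round is a happy, neutral or sad face determined by a
2x2 between-subject design (presence of positive feedback after
cooperation, presence of negative feedback after defection, conditions
1–4), crossed with a deception factor: half the participants are told the
opponent is human (game version 1), half that it is a computer (version 2).

## The strategy catalogue

Strategies are deterministic finite automata over the opponent's realised
actions. Every non-constant strategy in the catalogue is an instance of a
single trigger/release family — cooperate until the opponent defects
`trigger` times in a row, then defect until released (by one opponent
cooperation, by two in a row, or never) — which covers tit-for-tat and its
lenient variants (TF2T, TF3T), the punishing 2TFT and 2TF2T, and the Grim
triggers. Always-cooperate, always-defect and suspicious tit-for-tat
complete the set. The catalogue is a registry (`strategy_catalogue()`), and
`build_strategy_set("table6")` selects the four-strategy subset used for the
headline frequency table (TF3T, 2TF2T, Grim, ALLD), chosen to represent
cooperative, forgiving, unforgiving and defective play.

A deliberate design point: prescriptions condition on the *opponent's*
actions only. The rules the catalogue implements are phrased that way, and
it keeps every strategy a pure function of the joint history, which the
likelihood requires: a participant who trembled in round t is scored from
round t+1 onwards against what the strategy prescribes *given the realised
history*, not the counterfactual one.

## The tremble likelihood

Each round, a participant following strategy s executes its prescription
with probability beta and the opposite action with probability 1 − beta.
For a realised choice sequence with m~s~ mismatches against s's
prescriptions over T rounds, the likelihood is

P(choices | s, beta) = beta^(T − m~s~) (1 − beta)^m~s~.

The error is parameterised by a scale gamma through
beta = 1 / (1 + exp(−1/gamma)): gamma → 0 means perfect execution,
gamma = 1 corresponds to beta ≈ 0.73, and the fitting bracket
gamma ∈ [0.01, 5] spans beta from ~1 down to 0.55 (below 0.5 the "strategy"
would be executed less often than its opposite, which the model excludes).
Gamma is fitted by bounded scalar search (`stats::optimize`, tolerance
1e−6, endpoints checked explicitly because a perfectly consistent player
pushes the optimum onto the bracket edge).

## Two estimators of cohort strategy frequencies

`fit_subject()` fits each participant separately: gamma maximises the
uniform-prior mixture likelihood over the strategy set, and the reported
weights are the per-strategy likelihoods at that gamma, normalised to the
simplex. A literal per-subject mixture MLE is degenerate — the optimum
always sits on a simplex vertex — so fractional posterior weights are the
natural per-subject summary, and exact ties (strategies prescribing
identical play on the realised history) split weight equally.

Averaging those uniform-prior weights over the cohort
(`cohort_estimates()`) is transparent but *inconsistent* as a frequency
estimator: whenever several strategies prescribe similar play for most
participants, each such participant contributes near-uniform weight, and
the average is pulled towards the uniform mix regardless of the true one.
Our recovery simulations show this plainly — a strategy truly used by 1% of
a synthetic cohort is "recovered" at ~12% by subject-averaging.

The package therefore reports, as its headline estimate
(`strategy_estimates()`, estimator `"sfem"`), the population
strategy-frequency mixture MLE: maximise over the simplex phi and a common
gamma

sum~i~ log sum~s~ phi~s~ · beta^(T~i~ − m~is~) (1 − beta)^m~is~,

fitted by EM on phi (the closed-form posterior-mean update) alternated with
exact scalar search on gamma, with multi-start. This estimator is
consistent, and participants whose play is equally compatible with several
strategies simply contribute no information to their relative shares
instead of dragging them towards uniform. At the optimum phi equals the
cohort mean of the per-participant posterior adoption probabilities, so it
still reads as "the average over participants of the probability of
adopting each strategy", and the per-participant posteriors (returned as
`$posterior`) are what the trait–strategy correlations use. Standard errors
come from a nonparametric bootstrap over participants (B = 1000 by
default), refitting the mixture warm-started from the full-data solution;
p-values against zero use the one-sided normal approximation on
estimate/SE, with percentile intervals also reported. The subject-average
estimator remains available and every output labels which estimator
produced it.

## What the design can and cannot identify

Against this particular opponent, strategy identification has a structural
limit worth understanding before interpreting any frequency table. The
computer defects only when provoked (two consecutive participant
defections) or in the two endgame rounds. A participant playing TF3T,
2TF2T or ALLC therefore sees opponent defections only rarely, and within a
30-round horizon those three strategies prescribe *identical* actions
unless the participant trembles into two consecutive defections and then
defects again while being punished — roughly a 3% event per cooperative
participant at beta = 0.9. Their pairwise split is consequently almost
unidentified at realistic cohort sizes: in our 20-seed recovery experiments
(200 participants, beta = 0.9) the fitted 2TF2T and TF3T shares swing by
±0.2 in opposite directions while their *sum*, the ALLD share, the Grim
share, the ALLC share and the error scale are recovered well (gamma maps
back to beta within ±0.03 in every seed). Bootstrap SEs honestly reflect
this near-ridge in the likelihood: the confounded strategies carry much
larger SEs than ALLD. A longer horizon, or an opponent that defects
unprovoked mid-game, would separate them.

## Cooperation metrics and regressions

The two dependent variables are each participant's overall cooperation
rate and the count of cooperations immediately following the participant's
*own* previous cooperation (CaC; the opponent-conditioned variant is
provided separately for sensitivity analysis). CaC is handed to the
regressions as a proportion of the 29 possible transitions by default,
with the conditional normalisation (per previous own cooperation)
selectable; outputs record which was used. CaC after defection (CaD) is
computed symmetrically.

Three model families are candidates for each dependent variable: a
Gaussian identity-link linear model on the proportion scale, a binomial
logit on (successes, trials), and a beta-binomial with a dispersion
parameter fitted by direct likelihood maximisation (BFGS from the logistic
start; standard errors from the numerical Hessian). Selection uses
repeated k-fold cross-validation over participants — k = 5, 10 repeats by
default, seeded, with fold membership keyed to participants so the result
is invariant to row order — scoring held-out mean squared error of the
predicted mean response, the only loss comparable across the three
families on a common scale. Ties break by declared candidate order. The
interaction analysis fits, separately per dependent variable, one
interaction between the aggregate psychopathy score and each design
variable (game version, positive x negative feedback, positive feedback,
negative feedback), always with the control set of gender, game version,
maximise, narcissism and the condition dummies, including each
interaction's lower-order terms; collinear interactions (e.g. under a
constant trait) are flagged rather than silently dropped.

## Psychometric scoring

The 40-item psychopathy inventory is scored on a 1–4 scale with
reverse-keyed items flipped (r becomes 5 − r) and factor scores as item
sums. The instrument's own item key is licensed material, so the package
ships a structurally faithful default map and treats the map as a
replaceable configuration table. The default's factor item counts are
pinned by the published score ranges of the instrument's short form: a
fearless-dominance maximum of 56 is only reachable as 4 x 14 items, a
self-centred-impulsivity minimum of 16 as 1 x 16 items, and
coldheartedness spanning exactly 5–20 as 5 items; the remaining 5 of the
40 items are carried as a non-factor validity block. Narcissism is the
proportion of narcissism-consistent forced choices over 16 items (a
rescaling factor is exposed but defaults to the raw proportion, since the
transform behind published narcissism scores capped at 0.33 is not
documented). Participants scoring at or above 13 on the IRS-10
inconsistency screen are excluded before analysis; the attrition is logged
so a 233 → 206 → 192-style funnel is auditable. No missing items are
imputed anywhere: the analysis is complete-case.

## The synthetic cohort

The generator's defaults are the analysed sample's conditions: 192
participants (206 when emulating the pre-exclusion sample) in a balanced
2 (positive feedback) x 2 (negative feedback) x 2 (game version) design,
30 rounds, trait marginals matching the published sample moments
(fearless dominance 34.67 ± 7.51 on [17, 56], self-centred impulsivity
30.91 ± 5.89 on [16, 49], coldheartedness 10.78 ± 2.97 on [5, 20],
narcissism 0.08 ± 0.09 on [0, 0.33], maximise 4.26 ± 0.90 on 1–5, 112/192
female), strategies drawn from the estimated mix {ALLD 0.55, 2TF2T 0.22,
TF3T 0.15, Grim 0.07, ALLC 0.01}, and i.i.d. per-round trembles at the
compliance implied by the estimated error scale gamma = 0.88
(beta ≈ 0.757).

Numerical choices in the generator:

* Traits are truncated normals whose *parent* parameters are
  moment-matched so the truncated distribution attains the target mean and
  SD — using the targets as parent parameters would bias any trait whose
  bounds bite. The mean is weighted heavily and always attained; the SD is
  met exactly for the three factor scores but is infeasible within the
  family for narcissism (no truncated normal on [0, 0.33] with mean 0.08
  has SD 0.09; the generator attains ~0.071) and slightly under target for
  maximise before rounding. `maximise` is rounded to the 1–5 ordinal
  scale, which shifts its sample mean by about +0.05. The matching search
  is penalised to keep the truncation interval within 6.5 parent SDs,
  where the moment formulas and tail-aware inverse-CDF sampling are
  numerically exact.
* The synthetic IRS-10 score is a rounded truncated normal with parent
  mean 7 and SD 3.66 on [0, 30]; the SD was solved analytically so that
  the probability of scoring ≥ 13 equals the observed attrition rate
  14/206 ≈ 6.8%, which also places the cutoff near the instrument's 95th
  percentile.
* Traits are independent by default; an optional Gaussian-copula mode
  couples them through the published bivariate correlation matrix (e.g.
  fearless dominance–narcissism 0.40). The published moments and
  correlations do not determine a joint distribution, so the copula is a
  stand-in, not the data's model.
* Trembles are i.i.d. across rounds and independent of condition and
  feedback, consistent with the finding that feedback content did not
  move cooperation; a trait-to-strategy link (softmax tilt of the mix by
  standardised traits) is available to give recovery tests a known
  trait–strategy association, and is off by default.

What passing tests on this generator do and do not show: they validate the
estimators' statistical behaviour (bias, calibration, recovery) under the
model's own assumptions. Real participants are not finite automata with
i.i.d. trembles; in particular, synthetic CaC is mechanically coupled to
overall cooperation (correlation ≈ 0.98 in our runs) more tightly than
human play, where switching behaviour decouples the two. Regression
effects of traits on behaviour are absent by construction unless a trait
link is configured, so synthetic runs exercise the machinery and its
type-I calibration, not the sign or size of any trait effect.

## Problem sizes used by the test suite

Chosen to give each check adequate statistical resolution: exhaustive
automaton verification over all joint histories up to length 4; tremble
fits cross-checked against a gamma grid of step 0.01 on all instances with
T ≤ 4 and up to 3 strategies; trait-moment fidelity at n = 5000 (4 SE
bounds, since ~8 moments are checked at once); strategy-mix recovery at
200 participants x 30 rounds; regression type-I calibration with 500
replications of 500-participant null cohorts, where each covariate's
rejection rate at alpha = 0.05 must lie in [0.03, 0.07].

## Known limitations

* The 2TF2T/TF3T/ALLC ambiguity described above is a property of the
  design, not the estimator; frequency tables over those strategies should
  be read jointly with their bootstrap SEs.
* The beta-binomial family uses a numerical Hessian for SEs; under
  separation its mean is clamped to [1e−10, 1 − 1e−10] and a failed
  optimisation yields a flagged, not silent, result.
* The endgame defection is attributed to the computer only; with horizons
  other than 30 the two endgame rounds still feed the participant
  automaton's state through the realised history, which is the intended
  reading but matters only for longer horizons.
* Cronbach's alpha is provided as a utility for item blocks; the default
  item map is structurally faithful but not the licensed key, so alpha on
  synthetic item data says nothing about the real instrument.
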