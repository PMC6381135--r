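test_that("the gamma <-> beta mapping round-trips and brackets sensibly", {
  expect_equal(gamma_to_beta(beta_to_gamma(0.9)), 0.9, tolerance = 1e-12)
  expect_equal(beta_to_gamma(gamma_to_beta(0.88)), 0.88, tolerance = 1e-12)
  expect_gt(gamma_to_beta(0.999), plogis(1))  # gamma < 1 means beta > ~0.73
  expect_lt(gamma_to_beta(5), 0.56)
  expect_error(gamma_to_beta(-1), "positive")
  expect_error(beta_to_gamma(0.5), "beta")
})

test_that("the tremble likelihood is the match/mismatch product", {
  expect_equal(sequence_likelihood(rep("C", 5), rep("C", 5), 1), 1)
  expect_equal(sequence_likelihood(c("C", "D", "C"), c("C", "C", "D"), 0.5),
               0.5^3)
  expect_equal(sequence_likelihood(c("C", "D", "C"), c("C", "C", "C"), 0.8),
               0.8 * 0.2 * 0.8)
  expect_error(sequence_likelihood("C", c("C", "D"), 0.9), "equal length")
})

test_that("per-subject fits identify a perfectly consistent defector", {
  set <- build_strategy_set(c("ALLD", "ALLC"))
  sess <- data.frame(participant_action = rep("D", 30),
                     computer_action = c("C", "C", rep("D", 28)))
  fit <- fit_subject(sess, set)
  expect_gt(fit$weights[["ALLD"]], 0.99)
  expect_equal(fit$gamma_hat, 0.01)  # lower bracket edge: beta -> 1
  expect_equal(fit$best_strategy, "ALLD")
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("strategies prescribing identical play share weight equally", {
  # against an always-cooperating computer trace, Grim and TF3T prescribe
  # identically; the posterior cannot separate them
  set <- build_strategy_set(c("Grim", "TF3T"))
  sess <- data.frame(participant_action = c("C", "D", "C", "C"),
                     computer_action = rep("C", 4))
  fit <- fit_subject(sess, set)
  expect_equal(unname(fit$weights), c(0.5, 0.5))
})

test_that("per-subject fits match the exhaustive gamma-grid oracle", {
  sets <- list(build_strategy_set(c("ALLD", "ALLC")),
               build_strategy_set(c("TFT", "Grim", "ALLD")))
  comp <- c("C", "D", "C", "D")
  for (T in 2:4) for (choices in all_action_seqs(T)) {
    h <- joint_history(choices, comp[1:T], rounds_total = T)
    for (set in sets) {
      fit <- fit_subject(h, set)
      orc <- oracle_grid_fit(choices,
                             lapply(set, prescribed_sequence, history = h))
      expect_lt(max(abs(fit$weights - orc$weights)), 1e-3)
      # the continuous search can only improve on the grid optimum
      expect_gte(fit$loglik, orc$loglik - 1e-8)
    }
  }
})

test_that("a round matching one strategy raises its relative weight", {
  set <- build_strategy_set(c("ALLD", "ALLC"))
  # an imperfect defector (one tremble) keeps the optimum off the bracket
  # edge, so both weights stay positive
  mk <- function(extra) {
    acts <- c("D", "D", "C", "D", "D", extra)
    data.frame(participant_action = acts,
               computer_action = rep("C", length(acts)))
  }
  base <- fit_subject(mk(character(0)), set)
  more <- fit_subject(mk("D"), set)  # one more ALLD-consistent round
  expect_gt(more$weights[["ALLD"]] / more$weights[["ALLC"]],
            base$weights[["ALLD"]] / base$weights[["ALLC"]])
})

test_that("cohort estimates average the per-subject weights", {
  set <- build_strategy_set(c("ALLD", "ALLC"))
  rounds <- data.frame(
    participant_id = rep(1:2, each = 30),
    round = rep(1:30, 2),
    participant_action = c(rep("D", 30), rep("C", 30)),
    computer_action = rep(c("C", "C", rep("D", 28), rep("C", 28), "D", "D"), 1))
  fits <- fit_cohort(rounds, set)
  est <- cohort_estimates(fits)
  expect_equal(sum(est$frequencies), 1, tolerance = 1e-9)
  expect_equal(unname(est$frequencies), c(0.5, 0.5), tolerance = 0.01)
})

test_that("bootstrap SEs degenerate correctly and are seed-stable", {
  set <- build_strategy_set(c("ALLD", "ALLC"))
  # identical subjects: zero resampling variance, unmatched strategy p ~ 1
  rounds <- data.frame(
    participant_id = rep(1:20, each = 30),
    round = rep(1:30, 20),
    participant_action = rep("D", 600),
    computer_action = rep(c("C", "C", rep("D", 28)), 20))
  fits <- fit_cohort(rounds, set)
  bs <- bootstrap_se(fits, B = 200, seed = 1)
  expect_equal(unname(bs$se), c(0, 0))
  expect_equal(unname(bs$p[2]), 1)          # nobody plays ALLC
  expect_equal(unname(bs$stars[1]), "***")  # everyone plays ALLD

  set.seed(41)
  co <- generate_cohort(cohort_spec(n_participants = 60, tremble_beta = 0.9),
                        seed = 41)
  f2 <- fit_cohort(co$rounds, build_strategy_set("table6"))
  b1 <- bootstrap_se(f2, B = 1000, seed = 1)
  b2 <- bootstrap_se(f2, B = 1000, seed = 2)
  expect_lt(max(abs(b1$se - b2$se) / pmax(b1$se, 1e-6)), 0.15)
})

test_that("trait-weight correlations detect construction and degeneracy", {
  set.seed(42)
  n <- 2000
  traits <- data.frame(fearless_dominance = rnorm(n),
                       self_centred_impulsivity = rnorm(n),
                       coldheartedness = rnorm(n))
  w_alld <- runif(n)
  W <- cbind(ALLD = w_alld, ALLC = 1 - w_alld, NONE = rep(0.0, n))
  tc <- trait_strategy_correlations(W, traits)
  expect_true(all(abs(tc$r[, c("ALLD", "ALLC")]) < 0.08))
  expect_equal(tc$constant, "NONE")
  expect_true(all(is.na(tc$r[, "NONE"])))

  W2 <- cbind(ALLD = (traits$coldheartedness - min(traits$coldheartedness)) /
                diff(range(traits$coldheartedness)))
  tc2 <- trait_strategy_correlations(W2, traits)
  expect_equal(unname(tc2$r["coldheartedness", "ALLD"]), 1, tolerance = 1e-12)
})

test_that("the population mixture recovers identified quantities", {
  # a cleanly separated two-strategy cohort: population and subject-average
  # estimators agree and hit the generating mix
  spec <- cohort_spec(n_participants = 150,
                      strategy_mix = c(ALLD = 0.6, ALLC = 0.4),
                      tremble_beta = 0.9)
  co <- generate_cohort(spec, seed = 43)
  set2 <- build_strategy_set(c("ALLD", "ALLC"))
  sf <- sfem_population(co$rounds, set2, seed = 1)
  # compare against the realised assignment shares, the estimator's target
  realised <- table(factor(co$participants$strategy, c("ALLD", "ALLC"))) / 150
  expect_lt(max(abs(sf$phi - realised)), 0.05)
  expect_lt(abs(sf$beta - 0.9), 0.03)
  avg <- cohort_estimates(fit_cohort(co$rounds, set2))
  expect_lt(max(abs(sf$phi - avg$frequencies)), 0.10)

  one <- sfem_population(co$rounds, build_strategy_set("ALLD"), seed = 1)
  expect_equal(unname(one$phi), 1)
})

test_that("strategy_estimates reports the estimator used", {
  co <- generate_cohort(cohort_spec(n_participants = 40, tremble_beta = 0.9),
                        seed = 44)
  set4 <- build_strategy_set("table6")
  e1 <- strategy_estimates(co$rounds, set4, estimator = "sfem", B = 100, seed = 1)
  expect_equal(e1$estimator, "sfem")
  expect_equal(sum(e1$frequencies), 1, tolerance = 1e-6)
  expect_true(all(e1$se >= 0))
  e2 <- strategy_estimates(co$rounds, set4, estimator = "subject_average",
                           B = 100, seed = 1)
  expect_equal(e2$estimator, "subject_average")
  expect_equal(sum(e2$frequencies), 1, tolerance = 1e-9)
})
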