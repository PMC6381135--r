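test_that("trait marginals reproduce the target moments at n = 5000", {
  set.seed(21)
  spec <- cohort_spec()
  tr <- generate_traits(spec, n = 5000)
  tm <- spec$trait_moments
  for (i in seq_len(nrow(tm))) {
    v <- tr[[tm$trait[i]]]
    expect_gte(min(v), tm$min[i])
    expect_lte(max(v), tm$max[i])
    if (tm$trait[i] == "maximise") next  # rounded to the ordinal scale
    # 4 SE: ~8 moment checks run in this block, so a 3 SE bound
    # would false-alarm on ~2% of seeds
    expect_lt(abs(mean(v) - tm$mean[i]), 4 * tm$sd[i] / sqrt(5000))
  }
  # SDs of the three factor scores, whose targets the family can attain
  for (trait in c("fearless_dominance", "self_centred_impulsivity",
                  "coldheartedness")) {
    i <- match(trait, tm$trait)
    expect_lt(abs(sd(tr[[trait]]) - tm$sd[i]),
              4 * tm$sd[i] / sqrt(2 * 5000))
  }
  expect_lt(abs(mean(tr$gender == 1) - 112 / 192), 4 * 0.5 / sqrt(5000))
})

test_that("a zero-SD trait collapses to its mean and bad moments error", {
  tm <- default_trait_moments()
  tm$sd[tm$trait == "coldheartedness"] <- 0
  tr <- generate_traits(cohort_spec(trait_moments = tm), n = 50)
  expect_true(all(tr$coldheartedness == 10.78))
  tm2 <- default_trait_moments()
  tm2$min[1] <- tm2$max[1]
  expect_error(cohort_spec(trait_moments = tm2), "min must be below max")
  tm3 <- default_trait_moments()
  tm3$sd[2] <- -1
  expect_error(cohort_spec(trait_moments = tm3), "non-negative")
})

test_that("the copula mode induces the configured trait correlations", {
  set.seed(22)
  tr <- generate_traits(cohort_spec(copula = TRUE), n = 5000)
  R <- default_trait_correlations()
  got <- cor(tr$fearless_dominance, tr$narcissism)
  expect_lt(abs(got - R["fearless_dominance", "narcissism"]), 0.06)
  got2 <- cor(tr$self_centred_impulsivity, tr$coldheartedness)
  expect_lt(abs(got2 - R["self_centred_impulsivity", "coldheartedness"]), 0.06)
})

test_that("strategy assignment follows the mix, with optional trait links", {
  set.seed(23)
  spec1 <- cohort_spec(strategy_mix = c(ALLD = 1))
  tr1 <- generate_traits(spec1, n = 20)
  expect_true(all(assign_strategies(tr1, spec1) == "ALLD"))

  spec <- cohort_spec()
  tr <- generate_traits(spec, n = 5000)
  shares <- table(factor(assign_strategies(tr, spec),
                         levels = names(spec$strategy_mix))) / 5000
  expect_true(all(abs(shares - spec$strategy_mix) < 0.02))

  linked <- cohort_spec(
    trait_strategy_link = list(TF3T = c(coldheartedness = 1.5)))
  trl <- generate_traits(linked, n = 5000)
  s <- assign_strategies(trl, linked)
  expect_gt(cor(trl$coldheartedness, as.numeric(s == "TF3T")), 0)

  bad <- cohort_spec(trait_strategy_link = list(XXX = c(coldheartedness = 1)))
  expect_error(assign_strategies(trl, bad), "unknown strategy")
  expect_error(cohort_spec(strategy_mix = c(ALLD = 0.6, ALLC = 0.3)),
               "sum to 1")
})

test_that("trembled play matches prescriptions exactly when beta = 1", {
  set.seed(24)
  for (abbr in c("ALLC", "TFT", "2TF2T", "Grim", "ALLD")) {
    s <- build_strategy_set(abbr)[[1]]
    sess <- simulate_choices(s, beta = 1)
    h <- joint_history(sess$participant_action, sess$computer_action)
    expect_equal(sess$participant_action, prescribed_sequence(s, h))
  }
  allc <- simulate_choices(build_strategy_set("ALLC")[[1]], beta = 1)
  expect_equal(overall_cooperation(allc$participant_action), 1)
  expect_error(simulate_choices(build_strategy_set("ALLC")[[1]], beta = 0.4),
               "beta")
})

test_that("the vectorised simulator agrees with single-session play", {
  strategies <- names(build_strategy_set("full"))
  set.seed(25)
  sims <- ipdstrat:::simulate_sessions(strategies, beta = 1)
  for (i in seq_along(strategies)) {
    s <- build_strategy_set(strategies[i])[[1]]
    sess <- play_session(function(h) prescribe(s, h))
    expect_equal(unname(sims$participant[i, ]), sess$participant_action,
                 label = strategies[i])
    expect_equal(unname(sims$computer[i, ]), sess$computer_action,
                 label = strategies[i])
  }
})

test_that("the tremble rate matches 1 - beta", {
  set.seed(26)
  n <- 400  # 400 x 30 = 12000 rounds
  sims <- ipdstrat:::simulate_sessions(rep("TFT", n), beta = 0.9)
  s <- build_strategy_set("TFT")[[1]]
  dev <- vapply(seq_len(n), function(i) {
    h <- joint_history(sims$participant[i, ], sims$computer[i, ])
    sum(sims$participant[i, ] != prescribed_sequence(s, h))
  }, numeric(1))
  rate <- sum(dev) / (n * 30)
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("cohorts are balanced, complete and reproducible", {
  spec8 <- cohort_spec(n_participants = 8)
  co8 <- generate_cohort(spec8, seed = 5)
  cells <- table(co8$participants$condition, co8$participants$game_version)
  expect_true(all(cells == 1))

  spec <- cohort_spec()
  co <- generate_cohort(spec, seed = 5)
  expect_equal(nrow(co$rounds), 192 * 30)
  expect_equal(nrow(co$participants), 192)
  co2 <- generate_cohort(spec, seed = 5)
  expect_identical(co, co2)
  co3 <- generate_cohort(spec, seed = 6)
  expect_false(identical(co$rounds, co3$rounds))

  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  utils::write.csv(co$rounds, file.path(d1, "rounds.csv"), row.names = FALSE)
  utils::write.csv(co2$rounds, file.path(d2, "rounds.csv"), row.names = FALSE)
  expect_identical(readBin(file.path(d1, "rounds.csv"), "raw", 1e7),
                   readBin(file.path(d2, "rounds.csv"), "raw", 1e7))
})
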