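# Build a participant-summary-shaped table with a known generating model:
# cooperation counts are Binomial(30, p_i) with logit or identity link
# effects supplied by `lin`.
make_summary_data <- function(n, lin = function(d) rep(0.5, n), seed = 1) {
  set.seed(seed)
  d <- data.frame(
    participant_id = seq_len(n),
    gender = sample(1:2, n, replace = TRUE),
    maximise = sample(1:5, n, replace = TRUE),
    fearless_dominance = rnorm(n, 34.7, 7.5),
    self_centred_impulsivity = rnorm(n, 30.9, 5.9),
    coldheartedness = rnorm(n, 10.8, 3),
    narcissism = runif(n, 0, 0.33),
    game_version = sample(1:2, n, replace = TRUE),
    condition = sample(1:4, n, replace = TRUE),
    rounds_played = 30L)
  d <- cbind(d, factorial_encoding(d$condition))
  d$sum_psychopathic_traits <- sum_psychopathy(
    d$fearless_dominance, d$self_centred_impulsivity, d$coldheartedness)
  p <- pmin(pmax(lin(d), 0.02), 0.98)
  y <- rbinom(n, 30, p)
  d$cooperation <- y / 30
  d$cac_count <- rbinom(n, 29, p)
  d$cad_count <- pmax(0, 29 - d$cac_count - rbinom(n, 29, 0.5))
  d
}

test_that("condition ids map onto the factorial dummies", {
  enc <- factorial_encoding(1:4)
  expect_equal(enc$positive_feedback, c(0, 0, 1, 1))
  expect_equal(enc$negative_feedback, c(0, 1, 0, 1))
  expect_error(factorial_encoding(0), "condition id")
})

test_that("gaussian fits reproduce closed-form least squares", {
  d <- make_summary_data(3, seed = 2)
  d$cooperation <- c(10, 20, 26) / 30
  d$maximise <- c(1, 2, 4)
  fit <- fit_model(model_spec("gaussian_identity", "cooperation", "maximise"), d)
  beta <- oracle_ols(cbind(1, d$maximise), d$cooperation)
  expect_equal(fit$coefficients$estimate, unname(beta), tolerance = 1e-10)

  # intercept-only on a constant response
  dc <- make_summary_data(10, seed = 3)
  dc$cooperation <- 0.4
  fc <- suppressWarnings(
    fit_model(model_spec("gaussian_identity", "cooperation"), dc))
  expect_equal(fc$coefficients$estimate, 0.4)

  d2 <- make_summary_data(200, lin = function(d) 0.3 + 0.01 * d$coldheartedness,
                          seed = 4)
  f2 <- fit_model(model_spec("gaussian_identity", "cooperation",
                             c("coldheartedness", "maximise")), d2)
  X <- cbind(1, d2$coldheartedness, d2$maximise)
  expect_equal(f2$coefficients$estimate,
               unname(oracle_ols(X, round(d2$cooperation * 30) / 30)),
               tolerance = 1e-8)
})

test_that("the beta-binomial fit nests the binomial and improves its start", {
  d <- make_summary_data(150, lin = function(d) plogis(-0.5 + 0.03 * (d$coldheartedness - 10)),
                         seed = 5)
  bb <- fit_model(model_spec("beta_binomial", "cooperation", "coldheartedness"), d)
  bl <- fit_model(model_spec("binomial_logit", "cooperation", "coldheartedness"), d)
  # data are binomial, so the extra dispersion parameter should gain little
  # but never lose after accounting for the likelihood's constant terms
  expect_gte(bb$loglik, bl$loglik - 0.1)
  expect_lt(abs(bb$coefficients$estimate[2] - bl$coefficients$estimate[2]), 0.05)
  # the optimiser never ends below its starting log-likelihood
  expect_gte(bb$loglik, bb$model$start_loglik - 1e-8)
  expect_true(bb$converged)
})

test_that("the beta-binomial likelihood maximiser matches an independent fit", {
  skip_if_not_installed("glmmTMB")
  set.seed(6)
  n <- 120
  d <- make_summary_data(n, seed = 6)
  mu <- plogis(-0.3 + 0.05 * scale(d$coldheartedness)[, 1])
  phi <- 8
  p <- rbeta(n, mu * phi, (1 - mu) * phi)
  d$cooperation <- rbinom(n, 30, p) / 30
  bb <- fit_model(model_spec("beta_binomial", "cooperation", "coldheartedness"), d)
  y <- round(d$cooperation * 30)
  tmb <- glmmTMB::glmmTMB(cbind(y, 30 - y) ~ coldheartedness, data = d,
                          family = glmmTMB::betabinomial())
  expect_equal(bb$coefficients$estimate,
               unname(glmmTMB::fixef(tmb)$cond), tolerance = 1e-3)
  expect_equal(bb$loglik, as.numeric(stats::logLik(tmb)), tolerance = 1e-4)
})

test_that("cross-validation selects the generating family and is order-invariant", {
  # response generated from a Gaussian linear model on the proportion scale,
  # with a wide mean range so the logit family's curvature misfits
  set.seed(7)
  d <- make_summary_data(400, seed = 7)
  d$coldheartedness <- runif(400, 2, 20)
  mu <- 0.1 + 0.045 * d$coldheartedness
  d$cooperation <- round(pmin(pmax(mu + rnorm(400, 0, 0.05), 0), 1) * 30) / 30
  specs <- lapply(c("gaussian_identity", "binomial_logit"),
                  model_spec, response = "cooperation",
                  terms = c("coldheartedness", "maximise"))
  cv <- cv_select(specs, d, k = 5, repeats = 3, seed = 11)
  expect_equal(cv$chosen_family, "gaussian_identity")

  shuffled <- d[sample(nrow(d)), ]
  cv2 <- cv_select(specs, shuffled, k = 5, repeats = 3, seed = 11)
  expect_equal(cv2$table$mean_mse, cv$table$mean_mse, tolerance = 1e-12)

  one <- cv_select(specs[1], d, k = 5, repeats = 2, seed = 1)
  expect_equal(one$chosen, 1L)
  tie <- cv_select(c(specs[1], specs[1]), d, k = 5, repeats = 2, seed = 1)
  expect_equal(tie$chosen, 1L)
})

test_that("interaction regressions recover a known effect and flag collinearity", {
  n <- 2000
  d <- make_summary_data(n, seed = 8)
  z <- d$sum_psychopathic_traits - mean(d$sum_psychopathic_traits)
  p <- pmin(pmax(0.45 + 0.002 * z * d$positive_feedback, 0.02), 0.98)
  d$cooperation <- rbinom(n, 30, p) / 30
  tab <- interaction_regressions(d, responses = "cooperation")
  focal <- tab[tab$interaction == "positive_feedback:sum_psychopathic_traits", ]
  expect_false(focal$flagged)
  expect_lt(abs(focal$estimate - 0.002), 3 * focal$se)

  dc <- d; dc$sum_psychopathic_traits <- 76.36
  tabc <- interaction_regressions(dc, responses = "cooperation")
  expect_true(all(tabc$flagged))
})

test_that("model fitting validates inputs", {
  d <- make_summary_data(20, seed = 9)
  expect_error(fit_model(model_spec("gaussian_identity", "cooperation",
                                    "no_such_column"), d),
               "missing columns")
  d$narcissism[3] <- NA
  expect_error(fit_model(model_spec("gaussian_identity", "cooperation",
                                    ipdstrat:::full_terms()), d),
               "complete cases")
})
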