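toy_map <- function(n_fd = 2, n_sci = 2, n_cold = 1, reverse = integer()) {
  n <- n_fd + n_sci + n_cold
  data.frame(item = seq_len(n),
             subscale = "toy",
             factor = rep(c("fearless_dominance", "self_centred_impulsivity",
                            "coldheartedness"), c(n_fd, n_sci, n_cold)),
             reverse_keyed = seq_len(n) %in% reverse,
             stringsAsFactors = FALSE)
}

test_that("factor scores sum items with reverse-keying on the 1-4 scale", {
  map <- toy_map()
  sc <- score_ppi(rep(1, 5), item_map = map)
  expect_equal(sc$fearless_dominance, 2)
  expect_equal(sc$self_centred_impulsivity, 2)
  expect_equal(sc$coldheartedness, 1)
  expect_equal(sc$sum_psychopathic_traits, 5)

  # reverse of 1 on a 1-4 scale is 4: items (4, 1) with item 2 reversed -> 8
  map2 <- data.frame(item = 1:2, subscale = "toy",
                     factor = "fearless_dominance",
                     reverse_keyed = c(FALSE, TRUE))
  expect_equal(score_ppi(c(4, 1), item_map = map2)$fearless_dominance, 8)

  expect_error(score_ppi(c(1, NA, 1, 1, 1), item_map = map), "item\\(s\\) 2")
  expect_error(score_ppi(c(0, 1, 1, 1, 1), item_map = map), "outside")
})

test_that("scoring is invariant to item order given the map", {
  map <- default_ppi_item_map()
  set.seed(3)
  resp <- matrix(sample(1:4, 200, replace = TRUE), nrow = 5)
  perm <- sample(40)
  sc1 <- score_ppi(resp, item_map = map)
  sc2 <- score_ppi(resp[, perm], item_map = map[match(perm, map$item), ] |>
                     transform(item = seq_len(40)))
  # permuting columns together with the map rows leaves scores unchanged
  expect_equal(sc1, sc2)
})

test_that("the default item map spans the observed factor ranges", {
  map <- default_ppi_item_map()
  expect_equal(nrow(map), 40)
  n_fd <- sum(map$factor == "fearless_dominance")
  n_sci <- sum(map$factor == "self_centred_impulsivity")
  n_cold <- sum(map$factor == "coldheartedness")
  expect_equal(c(n_fd, n_sci, n_cold), c(14, 16, 5))
  # factor sum ranges [k, 4k] must cover the sample min/max of each factor
  expect_true(n_fd <= 17 && 4 * n_fd >= 56)
  expect_true(n_sci <= 16 && 4 * n_sci >= 49)
  expect_true(n_cold <= 5 && 4 * n_cold >= 20)
})

test_that("narcissism is the proportion of consistent choices", {
  expect_equal(score_npi(rep(0, 16)), 0)
  expect_equal(score_npi(rep(1, 16)), 1)
  expect_equal(score_npi(c(rep(1, 4), rep(0, 12))), 0.25)
  expect_equal(score_npi(c(rep(1, 4), rep(0, 12)), scale = 2), 0.5)
  expect_error(score_npi(rep(2, 16)), "0/1")
})

test_that("inconsistency exclusion uses a >= 13 cutoff and preserves order", {
  res <- apply_irs_exclusion(c(12, 13, 5, 14))
  expect_equal(res$retained, c(TRUE, FALSE, TRUE, FALSE))
  # a 206-strong cohort with exactly 14 high scores keeps 192
  irs <- c(rep(4, 192), rep(13:15, length.out = 14))
  expect_equal(apply_irs_exclusion(irs)$n_retained, 192)
  expect_equal(apply_irs_exclusion(irs)$n_excluded, 14)
  # raising the cutoff never removes more participants
  set.seed(9)
  scores <- sample(0:20, 100, replace = TRUE)
  kept <- vapply(10:18, function(k) apply_irs_exclusion(scores, k)$n_retained,
                 numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("the aggregate psychopathy score is the sum of the three factors", {
  expect_equal(sum_psychopathy(0, 0, 0), 0)
  expect_equal(sum_psychopathy(34.67, 30.91, 10.78), 76.36)
  expect_equal(sum_psychopathy(17, 16, 5), 38)
})

test_that("scored cohorts round-trip through CSV unchanged", {
  set.seed(11)
  resp <- matrix(sample(1:4, 400, replace = TRUE), nrow = 10)
  sc <- score_ppi(resp)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(sc, path, row.names = FALSE)
  expect_equal(utils::read.csv(path), sc)
})

test_that("alpha for two items equals the standardised two-item formula", {
  set.seed(4)
  x <- rnorm(200)
  items <- cbind(x + rnorm(200), x + rnorm(200))
  r <- cor(items[, 1], items[, 2])
  expect_equal(cronbach_alpha(scale(items)), 2 * r / (1 + r), tolerance = 1e-10)
  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "constant")
})
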