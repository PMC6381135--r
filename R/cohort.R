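# Moments of a truncated normal with parent (mu, sigma) on [a, b]. The
# normalising mass is computed in whichever tail keeps precision.
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- if (al > 0) {
    stats::pnorm(al, lower.tail = FALSE) - stats::pnorm(be, lower.tail = FALSE)
  } else {
    stats::pnorm(be) - stats::pnorm(al)
  }
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Find parent (mu, sigma) so the [a, b]-truncated normal has the target
# sample mean and SD. Matching on the truncated moments (rather than using
# the targets as parent parameters) matters where the bounds bite, e.g. a
# narcissism score with mean 0.08 and SD 0.09 on [0, 0.33]. The search is
# penalised to keep the truncation interval within 6.5 parent SDs, where
# the moment formulas and inverse-CDF sampling are numerically stable; a
# target SD unattainable inside that family is met as closely as possible
# (the attained moments are returned alongside the parameters).
truncnorm_match <- function(mean, sd, lower, upper) {
  key <- paste(mean, sd, lower, upper, sep = "|")
  hit <- .truncnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(p) {
    sigma <- exp(p[2])
    al <- (lower - p[1]) / sigma
    be <- (upper - p[1]) / sigma
    if (!is.finite(al) || !is.finite(be) || be - al < 1e-6) return(1e6)
    pen <- 1e3 * (max(0, al - 6.5)^2 + max(0, -be - 6.5)^2)
    if (al > 8 || be < -8) return(1e6 + pen)
    m <- truncnorm_moments(p[1], sigma, lower, upper)
    # the mean is the primary moment: pin it hard, meet the SD as closely
    # as the family allows
    100 * (m["mean"] - mean)^2 / sd^2 + (m["sd"] - sd)^2 / sd^2 + pen
  }
  starts <- list(c(mean, log(sd)),
                 c((lower + upper) / 2, log((upper - lower) / 4)))
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  got <- truncnorm_moments(mu, sigma, lower, upper)
  if (abs(got["mean"] - mean) > 0.02 * sd) {
    warning("truncated-normal moment matching could not reach target mean ",
            mean, " on [", lower, ", ", upper, "]")
  }
  out <- list(mu = mu, sigma = sigma,
              attained_mean = unname(got["mean"]), attained_sd = unname(got["sd"]))
  .truncnorm_cache[[key]] <- out
  out
}

# solved parameters are deterministic in their targets, so cache them
.truncnorm_cache <- new.env(parent = emptyenv())

# Quantile function of the truncated normal, evaluated in the numerically
# favourable tail so intervals deep in a parent tail keep full precision.
qtruncnorm <- function(p, mu, sigma, a, b) {
  if (a > mu) {
    ca <- stats::pnorm(a, mu, sigma, lower.tail = FALSE)
    cb <- stats::pnorm(b, mu, sigma, lower.tail = FALSE)
    stats::qnorm(ca - p * (ca - cb), mu, sigma, lower.tail = FALSE)
  } else {
    plo <- stats::pnorm(a, mu, sigma); phi <- stats::pnorm(b, mu, sigma)
    stats::qnorm(plo + p * (phi - plo), mu, sigma)
  }
}

#' Default trait moments of the analysed sample
#'
#' Sample minimum, mean, standard deviation and maximum of the five
#' participant-level measures the cooperation analysis conditions on.
#'
#' @return A data frame with one row per trait.
#' @export
default_trait_moments <- function() {
  data.frame(
    trait = c("fearless_dominance", "self_centred_impulsivity",
              "coldheartedness", "narcissism", "maximise"),
    mean = c(34.67, 30.91, 10.78, 0.08, 4.26),
    sd   = c(7.51, 5.89, 2.97, 0.09, 0.90),
    min  = c(17, 16, 5, 0, 1),
    max  = c(56, 49, 20, 0.33, 5),
    stringsAsFactors = FALSE
  )
}

#' Default trait correlation matrix for the copula mode
#'
#' Pairwise correlations among the five traits, as observed in the analysed
#' sample; used as the Gaussian-copula correlation when
#' `copula = TRUE` in [cohort_spec()].
#'
#' @return A 5x5 correlation matrix.
#' @export
default_trait_correlations <- function() {
  tr <- c("fearless_dominance", "self_centred_impulsivity",
          "coldheartedness", "narcissism", "maximise")
  R <- diag(5)
  dimnames(R) <- list(tr, tr)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("fearless_dominance", "self_centred_impulsivity", -0.07)
  set_r("fearless_dominance", "coldheartedness", 0.13)
  set_r("fearless_dominance", "narcissism", 0.40)
  set_r("fearless_dominance", "maximise", 0.01)
  set_r("self_centred_impulsivity", "coldheartedness", 0.28)
  set_r("self_centred_impulsivity", "narcissism", 0.25)
  set_r("self_centred_impulsivity", "maximise", -0.01)
  set_r("coldheartedness", "narcissism", 0.27)
  set_r("coldheartedness", "maximise", 0.18)
  set_r("narcissism", "maximise", -0.01)
  R
}

#' Default strategy mix of the analysed cohort
#'
#' The estimated shares of the four headline strategies, with the residual
#' share on always-cooperate so the mix spans nice, forgiving, unforgiving
#' and defective play.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_strategy_mix <- function() {
  c(ALLD = 0.55, `2TF2T` = 0.22, TF3T = 0.15, Grim = 0.07, ALLC = 0.01)
}

#' Specification of a synthetic cohort
#'
#' Collects everything the generator needs: cohort size, trait moments,
#' the strategy mix participants draw their automaton from, the tremble
#' compliance probability beta (each round the assigned strategy's
#' prescription is played with probability beta, the opposite action with
#' 1 - beta), optional trait-to-strategy link coefficients, and the game
#' configuration. The default beta is the compliance implied by the
#' study's estimated error scale gamma = 0.88 via beta = 1/(1+exp(-1/gamma)).
#'
#' @param n_participants cohort size (192 in the experiment).
#' @param trait_moments data frame as [default_trait_moments()].
#' @param female_share probability of gender code 1 (112/192 observed).
#' @param strategy_mix named weights over catalogue abbreviations, summing
#'   to 1.
#' @param tremble_beta compliance probability in (0.5, 1].
#' @param trait_strategy_link optional named list: for each strategy
#'   abbreviation, a named vector of log-odds coefficients on standardised
#'   traits that tilt the assignment (softmax over `log(mix) + X z`).
#' @param copula if `TRUE`, draw traits from a Gaussian copula with
#'   `trait_correlations`; otherwise independent marginals.
#' @param trait_correlations correlation matrix for the copula mode.
#' @param irs_mean,irs_sd parent moments of the synthetic IRS-10
#'   inconsistency score (rounded truncated normal on `[0, 30]`); the
#'   defaults place 6.8% of the population at or above the exclusion
#'   cutoff of 13, the attrition rate observed in the experiment (14 of
#'   206), which also puts the cutoff near the instrument's 95th
#'   percentile.
#' @param rounds_total,endgame_defect_rounds game horizon parameters.
#' @return An object of class `ipd_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 192L,
                        trait_moments = default_trait_moments(),
                        female_share = 112 / 192,
                        strategy_mix = default_strategy_mix(),
                        tremble_beta = gamma_to_beta(0.88),
                        trait_strategy_link = NULL,
                        copula = FALSE,
                        trait_correlations = default_trait_correlations(),
                        irs_mean = 7, irs_sd = 3.66,
                        rounds_total = 30L, endgame_defect_rounds = 2L) {
  abort_if(n_participants < 1, "n_participants must be positive")
  abort_if(any(strategy_mix < 0), "strategy weights must be non-negative")
  abort_if(abs(sum(strategy_mix) - 1) > 1e-9, "strategy weights must sum to 1")
  abort_if(is.null(names(strategy_mix)), "strategy_mix must be named")
  # validates the abbreviations
  build_strategy_set(names(strategy_mix))
  abort_if(!(tremble_beta > 0.5 && tremble_beta <= 1),
           "tremble_beta must lie in (0.5, 1]")
  need <- c("trait", "mean", "sd", "min", "max")
  abort_if(!all(need %in% names(trait_moments)),
           "trait_moments must have columns trait, mean, sd, min, max")
  abort_if(any(trait_moments$sd < 0), "trait SDs must be non-negative")
  abort_if(any(trait_moments$min >= trait_moments$max),
           "trait min must be below max")
  structure(list(n_participants = as.integer(n_participants),
                 trait_moments = trait_moments,
                 female_share = female_share,
                 strategy_mix = strategy_mix,
                 tremble_beta = tremble_beta,
                 trait_strategy_link = trait_strategy_link,
                 copula = copula,
                 trait_correlations = trait_correlations,
                 irs_mean = irs_mean, irs_sd = irs_sd,
                 rounds_total = as.integer(rounds_total),
                 endgame_defect_rounds = as.integer(endgame_defect_rounds)),
            class = "ipd_cohort_spec")
}

#' Draw synthetic trait profiles
#'
#' Continuous traits come from truncated normal distributions whose parent
#' parameters are moment-matched so that the truncated mean and SD equal
#' the specified ones; `maximise` is additionally rounded to the 1-5 scale.
#' With `copula = TRUE` the marginals are coupled through a Gaussian copula
#' with the spec's trait correlation matrix. Gender is Bernoulli with the
#' spec's female share (codes 1 = female, 2 = male) and the IRS-10
#' inconsistency score is a rounded truncated normal.
#'
#' @param spec an [cohort_spec()].
#' @param n number of profiles (defaults to the spec's cohort size).
#' @return Data frame with one row per participant.
#' @export
generate_traits <- function(spec, n = spec$n_participants) {
  tm <- spec$trait_moments
  k <- nrow(tm)
  pars <- lapply(seq_len(k), function(i) {
    if (tm$sd[i] == 0) return(list(mu = tm$mean[i], sigma = 0))
    truncnorm_match(tm$mean[i], tm$sd[i], tm$min[i], tm$max[i])
  })
  draws <- matrix(NA_real_, n, k, dimnames = list(NULL, tm$trait))
  if (spec$copula && k > 1) {
    R <- spec$trait_correlations[tm$trait, tm$trait]
    z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = R)
    u <- stats::pnorm(z)
    for (i in seq_len(k)) {
      if (pars[[i]]$sigma == 0) {
        draws[, i] <- tm$mean[i]
      } else {
        draws[, i] <- qtruncnorm(u[, i], pars[[i]]$mu, pars[[i]]$sigma,
                                 tm$min[i], tm$max[i])
      }
    }
  } else {
    for (i in seq_len(k)) {
      draws[, i] <- if (pars[[i]]$sigma == 0) rep(tm$mean[i], n) else
        rtruncnorm(n, pars[[i]]$mu, pars[[i]]$sigma, tm$min[i], tm$max[i])
    }
  }
  out <- as.data.frame(draws)
  if ("maximise" %in% names(out)) {
    out$maximise <- as.integer(pmin(pmax(round(out$maximise), 1), 5))
  }
  out$gender <- ifelse(stats::runif(n) < spec$female_share, 1L, 2L)
  out$irs10 <- as.integer(round(rtruncnorm(n, spec$irs_mean, spec$irs_sd, 0, 30)))
  if (all(c("fearless_dominance", "self_centred_impulsivity",
            "coldheartedness") %in% names(out))) {
    out$sum_psychopathic_traits <- sum_psychopathy(
      out$fearless_dominance, out$self_centred_impulsivity, out$coldheartedness)
  }
  out
}

#' Assign strategies to synthetic participants
#'
#' Without a trait link, i.i.d. draws from the spec's strategy mix. With a
#' link, participant i's assignment probabilities are
#' `softmax(log(mix) + sum_k coef[k, s] * z_ik)` where `z` are traits
#' standardised by the spec's moments — giving recovery tests a known
#' trait-strategy association.
#'
#' @param traits data frame from [generate_traits()].
#' @param spec an [cohort_spec()].
#' @return Character vector of strategy abbreviations.
#' @export
assign_strategies <- function(traits, spec) {
  n <- nrow(traits)
  mix <- spec$strategy_mix
  s_names <- names(mix)
  logits <- matrix(rep(log(pmax(mix, 1e-300)), each = n), n, length(mix),
                   dimnames = list(NULL, s_names))
  link <- spec$trait_strategy_link
  if (!is.null(link)) {
    tm <- spec$trait_moments
    for (s in names(link)) {
      abort_if(!s %in% s_names, sprintf("link names unknown strategy '%s'", s))
      for (tr in names(link[[s]])) {
        i <- match(tr, tm$trait)
        abort_if(is.na(i), sprintf("link names unknown trait '%s'", tr))
        z <- (traits[[tr]] - tm$mean[i]) / tm$sd[i]
        logits[, s] <- logits[, s] + link[[s]][[tr]] * z
      }
    }
  }
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  cum <- t(apply(probs, 1, cumsum))
  u <- stats::runif(n)
  idx <- rowSums(u > cum) + 1L
  s_names[idx]
}

# Vectorised simulation of many sessions in lock-step: participants play
# their assigned automaton with per-round tremble (compliance beta), the
# computer answers tit-for-two-tats with endgame defection. Returns
# character matrices [n x T] of realised actions.
simulate_sessions <- function(strategies, beta, rounds_total = 30L,
                              endgame_defect_rounds = 2L) {
  set <- build_strategy_set(unique(strategies))
  n <- length(strategies)
  T <- as.integer(rounds_total)
  meta <- do.call(rbind, lapply(set[strategies], function(s) {
    data.frame(first = s$first, always = ifelse(is.na(s$always), "", s$always),
               trigger = s$trigger, release = s$release,
               stringsAsFactors = FALSE)
  }))
  pa <- matrix(NA_character_, n, T)
  ca <- matrix(NA_character_, n, T)
  p_state <- automaton_init(n)   # participant automaton, observes computer
  c_state <- automaton_init(n)   # computer automaton, observes participant
  for (t in seq_len(T)) {
    presc <- if (t == 1L) meta$first else
      ifelse(meta$always != "", meta$always,
             ifelse(p_state$punish == 1L, "D", "C"))
    tremble <- stats::runif(n) > beta
    act <- ifelse(tremble, ifelse(presc == "C", "D", "C"), presc)
    comp <- if (t > T - endgame_defect_rounds) rep("D", n) else
      if (t == 1L) rep("C", n) else ifelse(c_state$punish == 1L, "D", "C")
    pa[, t] <- act
    ca[, t] <- comp
    p_state <- automaton_step(p_state, comp, meta$trigger, meta$release)
    c_state <- automaton_step(c_state, act, 2L, "one_coop")
  }
  list(participant = pa, computer = ca)
}

#' Simulate one participant's trembled session
#'
#' Plays a full game in which the participant follows `strategy`'s
#' prescription with probability `beta` each round and the opposite action
#' otherwise; future prescriptions condition on the realised (trembled)
#' history. The computer follows its scripted rule.
#'
#' @param strategy an `ipd_strategy`.
#' @param beta compliance probability in (0.5, 1].
#' @param config an [game_config()].
#' @return A round-record data frame as from [play_session()].
#' @export
simulate_choices <- function(strategy, beta, config = game_config()) {
  abort_if(!(beta > 0.5 && beta <= 1), "beta must lie in (0.5, 1]")
  policy <- function(h) {
    p <- prescribe(strategy, h)
    if (stats::runif(1) <= beta) p else if (p == "C") "D" else "C"
  }
  play_session(policy, config)
}

#' Generate a complete synthetic cohort
#'
#' Draws trait profiles, assigns conditions and game versions (balanced
#' across the 2x2x2 design — exactly equal cell counts when `n` is
#' divisible by 8), assigns strategies, simulates every session with
#' trembles, and returns tidy participant- and round-level tables in the
#' same schemas the experimental data use.
#'
#' @param spec an [cohort_spec()].
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @return A list of class `ipd_cohort` with elements `participants` (one
#'   row per participant, including the true assigned strategy),
#'   `rounds` (one row per participant x round) and `spec`, `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  n <- spec$n_participants
  traits <- generate_traits(spec, n)
  cells <- expand.grid(condition = 1:4, game_version = 1:2)
  assign_idx <- sample(rep(seq_len(nrow(cells)), length.out = n))
  cond_id <- cells$condition[assign_idx]
  gversion <- cells$game_version[assign_idx]
  strategies <- assign_strategies(traits, spec)
  sims <- simulate_sessions(strategies, spec$tremble_beta,
                            spec$rounds_total, spec$endgame_defect_rounds)
  pm <- payoff_matrix()
  T <- spec$rounds_total
  pid <- seq_len(n)
  rounds <- data.frame(
    participant_id = rep(pid, each = T),
    round = rep(seq_len(T), times = n),
    condition = rep(cond_id, each = T),
    game_version = rep(gversion, each = T),
    participant_action = as.vector(t(sims$participant)),
    computer_action = as.vector(t(sims$computer)),
    stringsAsFactors = FALSE
  )
  pay <- payoff(rounds$participant_action, rounds$computer_action, pm)
  rounds$participant_payoff <- pay$own
  rounds$computer_payoff <- pay$opp
  pos <- as.integer(rounds$condition %in% c(3L, 4L))
  neg <- as.integer(rounds$condition %in% c(2L, 4L))
  rounds$feedback <- ifelse(rounds$participant_action == "C",
                            ifelse(pos == 1L, "happy", "neutral"),
                            ifelse(neg == 1L, "sad", "neutral"))
  participants <- cbind(
    data.frame(participant_id = pid),
    traits,
    data.frame(condition = cond_id,
               game_version = gversion,
               positive_feedback = as.integer(cond_id %in% c(3L, 4L)),
               negative_feedback = as.integer(cond_id %in% c(2L, 4L)),
               strategy = strategies,
               tremble_beta = spec$tremble_beta,
               retained = apply_irs_exclusion(traits$irs10)$retained,
               stringsAsFactors = FALSE)
  )
  structure(list(participants = participants, rounds = rounds,
                 spec = spec, seed = as.integer(seed)),
            class = "ipd_cohort")
}

#' @export
print.ipd_cohort <- function(x, ...) {
  cat(sprintf("<ipd_cohort: %d participants x %d rounds, seed %d>\n",
              nrow(x$participants), x$spec$rounds_total, x$seed))
  invisible(x)
}
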