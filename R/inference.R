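#' Convert between the error scale gamma and compliance beta
#'
#' The tremble model's compliance probability (the chance of executing the
#' prescribed action in a round) is parameterised by an error scale gamma
#' through `beta = 1 / (1 + exp(-1/gamma))`. As gamma tends to 0 the player
#' executes perfectly (beta -> 1); gamma below 1 corresponds to compliance
#' above `plogis(1)` ~ 0.73 and is read as a good approximation of the
#' player by the assigned strategy.
#'
#' @param gamma positive error scale.
#' @param beta compliance probability in (0.5, 1).
#' @return The transformed parameter.
#' @export
gamma_to_beta <- function(gamma) {
  abort_if(any(gamma <= 0), "gamma must be positive")
  1 / (1 + exp(-1 / gamma))
}

#' @rdname gamma_to_beta
#' @export
beta_to_gamma <- function(beta) {
  abort_if(any(beta <= 0.5 | beta >= 1), "beta must lie in (0.5, 1)")
  1 / stats::qlogis(beta)
}

#' Tremble likelihood of a choice sequence
#'
#' Product over rounds of `beta` when the realised choice matches the
#' strategy's prescription and `1 - beta` otherwise.
#'
#' @param choices realised actions.
#' @param prescriptions prescribed actions, same length.
#' @param beta compliance probability in (0, 1].
#' @return Likelihood in `[0, 1]`.
#' @export
sequence_likelihood <- function(choices, prescriptions, beta) {
  choices <- as_actions(choices)
  prescriptions <- as_actions(prescriptions, "prescriptions")
  abort_if(length(choices) != length(prescriptions),
           "choices and prescriptions must have equal length")
  abort_if(length(choices) < 1, "need at least one round")
  abort_if(!(beta > 0 && beta <= 1), "beta must lie in (0, 1]")
  m <- sum(choices != prescriptions)
  T <- length(choices)
  beta^(T - m) * (1 - beta)^m
}

# Mismatch counts of a realised session against each strategy's
# prescriptions along the realised joint history.
mismatch_counts <- function(history, strategy_set) {
  vapply(strategy_set, function(s) {
    sum(prescribed_sequence(s, history) != history$own)
  }, numeric(1))
}

# Participant x strategy mismatch matrix from round-level data, plus the
# per-participant horizon. The sufficient statistics of the tremble model.
mismatch_matrix <- function(rounds, strategy_set) {
  ord <- order(rounds$participant_id, rounds$round)
  rounds <- rounds[ord, ]
  by_p <- split(rounds, rounds$participant_id)
  M <- do.call(rbind, lapply(by_p, function(d) {
    h <- joint_history(d$participant_action, d$computer_action,
                       rounds_total = max(nrow(d), 30L))
    mismatch_counts(h, strategy_set)
  }))
  rownames(M) <- names(by_p)
  list(M = M, T = vapply(by_p, nrow, numeric(1)),
       participant_id = names(by_p))
}

# Uniform-prior mixture log-likelihood at mismatch counts m, horizon T.
mixture_loglik_gamma <- function(gamma, m, T) {
  beta <- gamma_to_beta(gamma)
  log(mean(beta^(T - m) * (1 - beta)^m))
}

#' Fit the tremble model to one participant
#'
#' Computes each catalogued strategy's prescription sequence along the
#' participant's realised joint history, then maximises the uniform-prior
#' mixture likelihood over the error scale gamma by bounded scalar search.
#' The reported strategy weights are the per-strategy likelihoods at the
#' fitted gamma, normalised to the simplex (a uniform-prior posterior): a
#' literal per-subject mixture MLE always degenerates to a simplex vertex,
#' whereas fractional weights average into fractional cohort frequencies.
#'
#' @param session a round-record data frame with columns
#'   `participant_action` and `computer_action` (rounds in order), or an
#'   [joint_history()].
#' @param strategy_set named list from [build_strategy_set()].
#' @param gamma_bounds search bracket for gamma; the default `[0.01, 5]`
#'   covers compliance beta from ~1 down to 0.55.
#' @param tol convergence tolerance of the scalar search.
#' @return A list of class `ipd_subject_fit`: `weights` (named, sums to 1),
#'   `gamma_hat`, `beta_hat`, `loglik`, `best_strategy`, `mismatches`,
#'   `T`, `degenerate` flag.
#' @export
fit_subject <- function(session, strategy_set, gamma_bounds = c(0.01, 5),
                        tol = 1e-6) {
  history <- if (inherits(session, "ipd_history")) session else {
    abort_if(!all(c("participant_action", "computer_action") %in% names(session)),
             "session must have participant_action and computer_action")
    joint_history(session$participant_action, session$computer_action,
                  rounds_total = max(nrow(session), 30L))
  }
  abort_if(length(strategy_set) < 1, "strategy set must be non-empty")
  T <- length(history$own)
  abort_if(T < 1, "session must contain at least one round")
  m <- mismatch_counts(history, strategy_set)

  opt <- stats::optimize(mixture_loglik_gamma, interval = gamma_bounds,
                         m = m, T = T, maximum = TRUE, tol = tol)
  # the optimum can sit on the bracket edge (e.g. a perfect match pushes
  # beta -> 1); compare the interior optimum against both endpoints
  cand <- c(opt$maximum, gamma_bounds)
  ll <- vapply(cand, mixture_loglik_gamma, numeric(1), m = m, T = T)
  gamma_hat <- cand[which.max(ll)]
  beta_hat <- gamma_to_beta(gamma_hat)

  lik <- beta_hat^(T - m) * (1 - beta_hat)^m
  degenerate <- !any(lik > 0)
  w <- if (degenerate) rep(1 / length(m), length(m)) else lik / sum(lik)
  names(w) <- names(strategy_set)
  structure(list(weights = w,
                 gamma_hat = gamma_hat,
                 beta_hat = beta_hat,
                 loglik = max(ll),
                 best_strategy = names(w)[which.max(w)],
                 mismatches = m, T = T,
                 degenerate = degenerate),
            class = "ipd_subject_fit")
}

#' @export
print.ipd_subject_fit <- function(x, ...) {
  cat(sprintf("<ipd_subject_fit: gamma = %.3f (beta = %.3f), best = %s>\n",
              x$gamma_hat, x$beta_hat, x$best_strategy))
  print(round(x$weights, 3))
  invisible(x)
}

#' Fit the tremble model to every participant in a cohort
#'
#' @param rounds round-level data frame (`participant_id`, `round`,
#'   `participant_action`, `computer_action`).
#' @param strategy_set named list from [build_strategy_set()].
#' @param ... passed to [fit_subject()].
#' @return A list of class `ipd_cohort_fit`: `weights` matrix (participant
#'   x strategy), `gamma_hat` and `loglik` vectors, `best_strategy`,
#'   `participant_id`, `strategy_set` names.
#' @export
fit_cohort <- function(rounds, strategy_set, ...) {
  ord <- order(rounds$participant_id, rounds$round)
  rounds <- rounds[ord, ]
  by_p <- split(rounds, rounds$participant_id)
  fits <- lapply(by_p, fit_subject, strategy_set = strategy_set, ...)
  structure(list(
    weights = do.call(rbind, lapply(fits, `[[`, "weights")),
    gamma_hat = vapply(fits, `[[`, numeric(1), "gamma_hat"),
    beta_hat = vapply(fits, `[[`, numeric(1), "beta_hat"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    best_strategy = vapply(fits, `[[`, character(1), "best_strategy"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    participant_id = names(by_p),
    strategies = names(strategy_set)), class = "ipd_cohort_fit")
}

#' Cohort-level strategy frequencies
#'
#' The estimated share of the cohort adopting each strategy is the mean of
#' the per-participant strategy weights; the cohort error scale is the mean
#' of the per-participant fitted gammas.
#'
#' @param fits an `ipd_cohort_fit` from [fit_cohort()].
#' @return A list of class `ipd_cohort_estimate`: `frequencies` (named,
#'   sums to 1), `gamma`, `n`.
#' @export
cohort_estimates <- function(fits) {
  abort_if(!inherits(fits, "ipd_cohort_fit"), "fits must be an ipd_cohort_fit")
  structure(list(frequencies = colMeans(fits$weights),
                 gamma = mean(fits$gamma_hat),
                 beta = mean(fits$beta_hat),
                 n = nrow(fits$weights)),
            class = "ipd_cohort_estimate")
}

#' Bootstrap standard errors for cohort strategy frequencies
#'
#' Resamples participants with replacement `B` times, recomputing the
#' cohort means of the per-participant weights and gammas. The standard
#' error is the standard deviation over replicates; the p-value tests
#' H0: frequency = 0 against frequency > 0 by the one-sided normal
#' approximation (estimate / SE). Percentile intervals are also returned.
#'
#' @param fits an `ipd_cohort_fit`.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param conf percentile-interval coverage.
#' @return A list of class `ipd_cohort_estimate` with `frequencies`, `se`,
#'   `p`, `stars`, `ci_lower`, `ci_upper`, `gamma`, `gamma_se`, `n`, `B`,
#'   `seed`.
#' @export
bootstrap_se <- function(fits, B = 1000L, seed = 1L, conf = 0.95) {
  abort_if(!inherits(fits, "ipd_cohort_fit"), "fits must be an ipd_cohort_fit")
  abort_if(B < 100, "B must be at least 100")
  set.seed(as.integer(seed))
  n <- nrow(fits$weights)
  S <- ncol(fits$weights)
  boot_freq <- matrix(NA_real_, B, S, dimnames = list(NULL, fits$strategies))
  boot_gamma <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_freq[b, ] <- colMeans(fits$weights[idx, , drop = FALSE])
    boot_gamma[b] <- mean(fits$gamma_hat[idx])
  }
  est <- colMeans(fits$weights)
  se <- apply(boot_freq, 2, stats::sd)
  z <- ifelse(se > 0, est / se, Inf)
  p <- ifelse(est == 0, 1, stats::pnorm(-z))
  alpha <- (1 - conf) / 2
  structure(list(frequencies = est, se = se, p = p, stars = p_stars(p),
                 ci_lower = apply(boot_freq, 2, stats::quantile, probs = alpha),
                 ci_upper = apply(boot_freq, 2, stats::quantile, probs = 1 - alpha),
                 gamma = mean(fits$gamma_hat), gamma_se = stats::sd(boot_gamma),
                 n = n, B = as.integer(B), seed = as.integer(seed)),
            class = "ipd_cohort_estimate")
}

#' @export
print.ipd_cohort_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Cohort strategy frequencies (n = %d%s), gamma = %.2f",
              x$n,
              if (!is.null(x$estimator)) paste0(", estimator = ", x$estimator) else "",
              x$gamma))
  if (!is.null(x$gamma_se)) cat(sprintf(" (%.2f)", x$gamma_se))
  cat("\n")
  tab <- data.frame(strategy = names(x$frequencies),
                    frequency = formatC(x$frequencies, digits = digits, format = "f"))
  if (!is.null(x$se)) {
    tab$se <- paste0("(", formatC(x$se, digits = digits, format = "f"), ")")
    tab$stars <- x$stars
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Correlations between strategy weights and psychopathy factors
#'
#' Pearson correlations between each strategy's per-participant weight and
#' the three psychopathy factor scores, with significance stars. Constant
#' weight columns are flagged and left `NA`.
#'
#' @param fits an `ipd_cohort_fit`.
#' @param traits participant-level data frame aligned with the fits (same
#'   participants, same order as `fits$participant_id`), carrying
#'   `fearless_dominance`, `self_centred_impulsivity`, `coldheartedness`.
#' @return A list of class `ipd_trait_cor` with matrices `r`, `p`, `stars`
#'   (trait x strategy) and `constant` strategy names.
#' @export
trait_strategy_correlations <- function(fits, traits) {
  W <- if (inherits(fits, "ipd_cohort_fit")) fits$weights else as.matrix(fits)
  abort_if(is.null(colnames(W)), "weights must have strategy column names")
  abort_if(nrow(traits) != nrow(W),
           "traits and fits cover different numbers of participants")
  trait_cols <- c("fearless_dominance", "self_centred_impulsivity",
                  "coldheartedness")
  abort_if(!all(trait_cols %in% names(traits)),
           "traits must carry the three psychopathy factor columns")
  S <- colnames(W)
  constant <- S[apply(W, 2, stats::sd) == 0]
  r <- matrix(NA_real_, length(trait_cols), length(S),
              dimnames = list(trait_cols, S))
  p <- r
  for (tr in trait_cols) for (s in S) {
    if (s %in% constant) next
    ct <- stats::cor.test(traits[[tr]], W[, s])
    r[tr, s] <- unname(ct$estimate)
    p[tr, s] <- ct$p.value
  }
  stars <- matrix(p_stars(p), nrow(r), ncol(r), dimnames = dimnames(r))
  structure(list(r = r, p = p, stars = stars, constant = constant),
            class = "ipd_trait_cor")
}

#' @export
print.ipd_trait_cor <- function(x, digits = 2, ...) {
  cells <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                  nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  cells[is.na(x$r)] <- "NA"
  print(as.data.frame(cells), right = TRUE)
  cat("Significance: '***' < 0.001 '**' < 0.01 '*' < 0.05 '.' < 0.1\n")
  if (length(x$constant)) cat("Constant weights:", paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

# EM engine for the population mixture on precomputed mismatch counts M
# (participants x strategies) with horizons Tv. Alternates an exact scalar
# search on gamma with the closed-form simplex update. `weights` allows a
# weighted (e.g. bootstrap-resampled) likelihood without copying rows.
sfem_core <- function(M, Tv, phi0, gamma0 = 1, weights = NULL,
                      gamma_bounds = c(0.01, 5), max_iter = 2000L,
                      tol = 1e-8, gamma_every = 5L) {
  n <- nrow(M); S <- ncol(M)
  w <- weights %||% rep(1, n)
  wn <- sum(w)
  lik_matrix <- function(beta) beta^(Tv - M) * (1 - beta)^M
  mix_ll <- function(phi, beta) {
    sum(w * log(pmax(drop(lik_matrix(beta) %*% phi), 1e-300)))
  }
  phi <- phi0; gamma <- gamma0
  beta <- gamma_to_beta(gamma)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (it %% gamma_every == 1L) {
      opt <- stats::optimize(function(g) mix_ll(phi, gamma_to_beta(g)),
                             interval = gamma_bounds, maximum = TRUE)
      cand <- c(opt$maximum, gamma_bounds)
      lls <- vapply(cand, function(g) mix_ll(phi, gamma_to_beta(g)), numeric(1))
      gamma <- cand[which.max(lls)]
      beta <- gamma_to_beta(gamma)
    }
    L <- lik_matrix(beta)
    post <- L * rep(phi, each = n)
    post <- post / pmax(rowSums(post), 1e-300)
    phi <- colSums(post * w) / wn
    ll <- mix_ll(phi, beta)
    if (abs(ll - ll_old) < tol && it %% gamma_every == 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(phi = phi, gamma = gamma, beta = beta, loglik = ll,
       converged = converged, posterior = post)
}

#' Population-level strategy frequency estimation (SFEM)
#'
#' The population mixture estimator: maximises
#' `sum_i log sum_s phi_s * beta^(T_i - m_is) (1-beta)^m_is` over the
#' mixture proportions phi (simplex) and a common error scale gamma, by
#' expectation-maximisation on phi nested with bounded scalar search on
#' gamma, with seeded multi-start. The fitted phi equals the cohort mean of
#' the per-participant posterior adoption probabilities at the optimum, so
#' it reads directly as the share of the cohort adopting each strategy.
#'
#' @param rounds round-level data frame as in [fit_cohort()].
#' @param strategy_set named list from [build_strategy_set()].
#' @param gamma_bounds search bracket for gamma.
#' @param n_starts number of random restarts beyond the uniform start.
#' @param seed integer seed for the restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A list of class `ipd_sfem`: `phi` (named simplex), `gamma`,
#'   `beta`, `loglik`, `posterior` (participant x strategy adoption
#'   probabilities), `converged`, `n`.
#' @export
sfem_population <- function(rounds, strategy_set, gamma_bounds = c(0.01, 5),
                            n_starts = 3L, seed = 1L, max_iter = 2000L,
                            tol = 1e-8) {
  mm <- mismatch_matrix(rounds, strategy_set)
  abort_if(nrow(mm$M) < 2, "need at least two participants")
  S <- ncol(mm$M)
  set.seed(as.integer(seed))
  starts <- c(list(rep(1 / S, S)),
              lapply(seq_len(n_starts), function(i) {
                x <- stats::rexp(S); x / sum(x)
              }))
  runs <- lapply(starts, function(p0) {
    sfem_core(mm$M, mm$T, p0, gamma_bounds = gamma_bounds,
              max_iter = max_iter, tol = tol)
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  phi <- best$phi
  names(phi) <- names(strategy_set)
  posterior <- best$posterior
  dimnames(posterior) <- list(mm$participant_id, names(strategy_set))
  if (!best$converged) warning("SFEM did not converge within max_iter")
  structure(list(phi = phi, gamma = best$gamma, beta = best$beta,
                 loglik = best$loglik, posterior = posterior,
                 converged = best$converged,
                 n = nrow(mm$M), mismatches = mm$M, horizons = mm$T),
            class = "ipd_sfem")
}

#' Cohort strategy frequencies with bootstrap SEs
#'
#' The headline estimate: strategy adoption frequencies, their
#' bootstrapped standard errors and significance against zero, and the
#' cohort error scale gamma. Two estimators are available and the output
#' records which was used:
#' * `"sfem"` (default) — the population mixture MLE of
#'   [sfem_population()]; bootstrap replicates resample participants and
#'   refit the mixture warm-started from the full-data solution.
#' * `"subject_average"` — the mean of per-participant uniform-prior
#'   posterior weights from [fit_cohort()], with gamma the mean of the
#'   per-participant estimates. Simple and transparent, but shrunken
#'   towards the uniform mix when strategies prescribe similar play, so
#'   preferred only for descriptive per-subject reporting.
#'
#' @param rounds round-level data frame.
#' @param strategy_set named list from [build_strategy_set()].
#' @param estimator `"sfem"` or `"subject_average"`.
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param conf percentile-interval coverage.
#' @return An `ipd_cohort_estimate` (see [bootstrap_se()]) with an
#'   `estimator` field.
#' @export
strategy_estimates <- function(rounds, strategy_set,
                               estimator = c("sfem", "subject_average"),
                               B = 1000L, seed = 1L, conf = 0.95) {
  estimator <- match.arg(estimator)
  if (estimator == "subject_average") {
    fits <- fit_cohort(rounds, strategy_set)
    out <- bootstrap_se(fits, B = B, seed = seed, conf = conf)
    out$estimator <- "subject_average"
    return(out)
  }
  abort_if(B < 100, "B must be at least 100")
  full <- sfem_population(rounds, strategy_set, seed = seed)
  M <- full$mismatches; Tv <- full$horizons
  n <- nrow(M)
  set.seed(as.integer(seed) + 1L)
  boot_phi <- matrix(NA_real_, B, ncol(M),
                     dimnames = list(NULL, names(full$phi)))
  boot_gamma <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    w <- tabulate(idx, nbins = n)
    fit <- sfem_core(M, Tv, full$phi, gamma0 = full$gamma, weights = w,
                     max_iter = 500L, tol = 1e-7)
    boot_phi[b, ] <- fit$phi
    boot_gamma[b] <- fit$gamma
  }
  est <- full$phi
  se <- apply(boot_phi, 2, stats::sd)
  z <- ifelse(se > 0, est / se, Inf)
  p <- ifelse(est == 0, 1, stats::pnorm(-z))
  alpha <- (1 - conf) / 2
  structure(list(frequencies = est, se = se, p = p, stars = p_stars(p),
                 ci_lower = apply(boot_phi, 2, stats::quantile, probs = alpha),
                 ci_upper = apply(boot_phi, 2, stats::quantile, probs = 1 - alpha),
                 gamma = full$gamma, gamma_se = stats::sd(boot_gamma),
                 loglik = full$loglik,
                 n = n, B = as.integer(B), seed = as.integer(seed),
                 estimator = "sfem", sfem = full),
            class = "ipd_cohort_estimate")
}

#' @export
print.ipd_sfem <- function(x, ...) {
  cat(sprintf("SFEM population mixture (n = %d), gamma = %.2f, logLik = %.2f\n",
              x$n, x$gamma, x$loglik))
  print(round(x$phi, 3))
  invisible(x)
}
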