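#' Factorial encoding of a condition id
#'
#' Maps condition 1-4 to the 2x2 factorial dummies: 1 -> (0,0), 2 -> (0,1),
#' 3 -> (1,0), 4 -> (1,1) for (positive feedback, negative feedback).
#'
#' @param id integer vector of condition ids.
#' @return Data frame with columns `positive_feedback`, `negative_feedback`.
#' @export
factorial_encoding <- function(id) {
  id <- as.integer(id)
  abort_if(!all(id %in% 1:4), "condition id must be 1, 2, 3 or 4")
  data.frame(positive_feedback = as.integer(id %in% c(3L, 4L)),
             negative_feedback = as.integer(id %in% c(2L, 4L)))
}

#' Candidate model specification
#'
#' @param family `"gaussian_identity"` (linear model on the proportion-scale
#'   response), `"binomial_logit"` (logistic on successes out of trials) or
#'   `"beta_binomial"` (logit-mean beta-binomial with a dispersion
#'   parameter, fitted by direct likelihood maximisation).
#' @param response `"cooperation"`, `"cac"` or `"cad"`.
#' @param terms character vector of covariate names; interactions written
#'   with `:` (e.g. `"positive_feedback:negative_feedback"`).
#' @return An object of class `ipd_model_spec`.
#' @export
model_spec <- function(family = c("gaussian_identity", "binomial_logit", "beta_binomial"),
                       response = c("cooperation", "cac", "cad"),
                       terms = character()) {
  family <- match.arg(family)
  response <- match.arg(response)
  structure(list(family = family, response = response, terms = terms),
            class = "ipd_model_spec")
}

# The paper-style fixed covariate sets.
trait_terms <- function() {
  c("fearless_dominance", "self_centred_impulsivity", "coldheartedness",
    "narcissism")
}

full_terms <- function() {
  c("gender", "maximise", trait_terms(),
    "positive_feedback", "negative_feedback",
    "positive_feedback:negative_feedback", "game_version")
}

# Successes/trials for the count-based families.
response_counts <- function(spec, data) {
  T <- data$rounds_played
  abort_if(is.null(T), "data must carry a rounds_played column")
  switch(spec$response,
    cooperation = list(y = round(data$cooperation * T), n = T),
    cac = list(y = data$cac_count, n = T - 1L),
    cad = list(y = data$cad_count, n = T - 1L))
}

response_proportion <- function(spec, data) {
  cnt <- response_counts(spec, data)
  cnt$y / cnt$n
}

bb_negloglik <- function(par, X, y, n) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  # keep the likelihood finite under separation (fitted mu of 0 or 1)
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  phi <- exp(par[p + 1L])
  a <- mu * phi
  b <- (1 - mu) * phi
  -sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

#' Fit one candidate model
#'
#' Maximum-likelihood fit of the declared family with the declared terms.
#' The Gaussian family is an identity-link linear model on the
#' proportion-scale response; the logistic family models (successes,
#' trials); the beta-binomial adds a dispersion parameter and is maximised
#' directly with `optim` (BFGS, initialised from the logistic fit),
#' standard errors from the numerical Hessian.
#'
#' @param spec an [model_spec()].
#' @param data participant-summary data frame (see
#'   [participant_summaries()]), complete cases.
#' @return A list of class `ipd_fit`: `coefficients` data frame (term,
#'   estimate, se, p, stars), `loglik`, `n`, `family`, `response`,
#'   `converged`, and the underlying `model` object where one exists.
#' @export
fit_model <- function(spec, data) {
  abort_if(!inherits(spec, "ipd_model_spec"), "spec must be an ipd_model_spec")
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  plain_vars <- unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))
  missing_terms <- setdiff(plain_vars, names(data))
  abort_if(length(missing_terms) > 0, sprintf(
    "terms reference missing columns: %s", paste(missing_terms, collapse = ", ")))
  cc_cols <- c(plain_vars, "rounds_played", "cooperation", "cac_count", "cad_count")
  cc_cols <- intersect(cc_cols, names(data))
  abort_if(any(!stats::complete.cases(data[cc_cols])),
           "data must be complete cases for all model columns")
  prop <- response_proportion(spec, data)
  cnt <- response_counts(spec, data)
  abort_if(nrow(data) <= length(spec$terms) + 1,
           "more terms than observations")

  if (spec$family == "gaussian_identity") {
    d <- data; d$.y <- prop
    fml <- stats::as.formula(paste(".y ~", rhs))
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        p = sm[, 4], stringsAsFactors = FALSE)
    ll <- as.numeric(stats::logLik(fit))
    converged <- TRUE
    model <- fit
  } else if (spec$family == "binomial_logit") {
    d <- data; d$.y <- cnt$y; d$.n <- cnt$n
    fml <- stats::as.formula(paste("cbind(.y, .n - .y) ~", rhs))
    fit <- stats::glm(fml, family = stats::binomial(), data = d)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        p = sm[, 4], stringsAsFactors = FALSE)
    ll <- as.numeric(stats::logLik(fit))
    converged <- fit$converged
    model <- fit
  } else {
    fml <- stats::as.formula(paste("~", rhs))
    X <- stats::model.matrix(fml, data = data)
    init_glm <- stats::glm.fit(X, cbind(cnt$y, cnt$n - cnt$y),
                               family = stats::binomial())
    start <- c(init_glm$coefficients, log_phi = log(50))
    start[is.na(start) | !is.finite(start)] <- 0
    opt <- tryCatch(
      stats::optim(start, bb_negloglik, X = X, y = cnt$y, n = cnt$n,
                   method = "BFGS", hessian = TRUE,
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    p <- ncol(X)
    if (is.null(opt)) {
      est <- rep(NA_real_, p); se <- rep(NA_real_, p)
      ll <- NA_real_; converged <- FALSE
      model <- NULL
      z <- rep(NA_real_, p)
    } else {
      est <- opt$par[seq_len(p)]
      se <- rep(NA_real_, p)
      vc <- try(solve(opt$hessian), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc)[seq_len(p)] > 0)) {
        se <- sqrt(diag(vc)[seq_len(p)])
      }
      z <- est / se
      ll <- -opt$value
      converged <- opt$convergence == 0
      model <- list(par = opt$par, X_terms = colnames(X), formula = fml,
                    phi = exp(opt$par[p + 1L]),
                    start_loglik = -bb_negloglik(start, X, cnt$y, cnt$n))
    }
    coefs <- data.frame(term = colnames(X), estimate = est, se = se,
                        p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  coefs$stars <- p_stars(coefs$p)
  rownames(coefs) <- NULL
  if (!converged) warning("model fit did not converge (", spec$family, ")")
  structure(list(coefficients = coefs, loglik = ll, n = nrow(data),
                 family = spec$family, response = spec$response,
                 terms = spec$terms, converged = converged, model = model),
            class = "ipd_fit")
}

#' @export
print.ipd_fit <- function(x, digits = 2, ...) {
  cat(sprintf("%s fit, response = %s, n = %d, logLik = %.2f%s\n",
              x$family, x$response, x$n, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- x$coefficients
  tab$estimate <- formatC(tab$estimate, digits = digits, format = "f")
  tab$se <- paste0("(", formatC(tab$se, digits = digits, format = "f"), ")")
  print(tab[, c("term", "estimate", "se", "stars")], row.names = FALSE)
  invisible(x)
}

# Mean-response prediction on new data, comparable across families.
predict_mean <- function(fit, newdata) {
  if (fit$family == "gaussian_identity") {
    return(unname(stats::predict(fit$model, newdata = newdata)))
  }
  if (fit$family == "binomial_logit") {
    return(unname(stats::predict(fit$model, newdata = newdata, type = "response")))
  }
  X <- stats::model.matrix(fit$model$formula, data = newdata)
  p <- length(fit$model$X_terms)
  stats::plogis(drop(X %*% fit$model$par[seq_len(p)]))
}

#' Select a model family by repeated k-fold cross-validation
#'
#' Participants are partitioned into `k` folds; each candidate family is
#' fitted on the training folds and scored by mean squared error of the
#' predicted mean response against the held-out observed proportions. The
#' partitioning is repeated `repeats` times with reshuffling, fully seeded.
#' The family with the lowest mean held-out error wins; ties break by the
#' declared candidate order.
#'
#' @param specs list of [model_spec()]s (same response, different families).
#' @param data participant-summary data frame.
#' @param k number of folds (default 5).
#' @param repeats number of reshuffled repetitions (default 10).
#' @param seed integer seed.
#' @return A list of class `ipd_cv`: `table` (per-candidate mean and SD of
#'   fold MSE), `chosen` (index), `chosen_family`, `k`, `repeats`, `seed`,
#'   `flags` (fold-level fit warnings).
#' @export
cv_select <- function(specs, data, k = 5L, repeats = 10L, seed = 1L) {
  abort_if(length(specs) < 1, "need at least one candidate")
  abort_if(k < 2, "k must be at least 2")
  n <- nrow(data)
  abort_if(n < k, "fewer participants than folds")
  set.seed(as.integer(seed))
  errs <- matrix(NA_real_, nrow = repeats * k, ncol = length(specs))
  flags <- character(0)
  row <- 0L
  # fold membership follows participants, not row positions, so the
  # selection is invariant to row order under a fixed seed
  key <- if ("participant_id" %in% names(data)) rank(data$participant_id) else
    seq_len(n)
  for (r in seq_len(repeats)) {
    fold <- sample(rep(seq_len(k), length.out = n))[key]
    for (f in seq_len(k)) {
      row <- row + 1L
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      for (s in seq_along(specs)) {
        obs <- response_proportion(specs[[s]], test)
        fit <- tryCatch(suppressWarnings(fit_model(specs[[s]], train)),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          flags <- c(flags, sprintf("repeat %d fold %d candidate %d: %s",
                                    r, f, s, conditionMessage(fit)))
          next
        }
        if (!fit$converged) {
          flags <- c(flags, sprintf("repeat %d fold %d candidate %d: not converged",
                                    r, f, s))
        }
        if (is.null(fit$model)) next
        pred <- predict_mean(fit, test)
        errs[row, s] <- mean((pred - obs)^2)
      }
    }
  }
  mean_err <- colMeans(errs, na.rm = TRUE)
  sd_err <- apply(errs, 2, stats::sd, na.rm = TRUE)
  chosen <- which(mean_err == min(mean_err))[1]
  structure(list(
    table = data.frame(family = vapply(specs, `[[`, character(1), "family"),
                       response = vapply(specs, `[[`, character(1), "response"),
                       mean_mse = mean_err, sd_mse = sd_err),
    chosen = chosen,
    chosen_family = specs[[chosen]]$family,
    k = as.integer(k), repeats = as.integer(repeats), seed = as.integer(seed),
    flags = flags), class = "ipd_cv")
}

#' @export
print.ipd_cv <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV (%d repeats, seed %d)\n", x$k, x$repeats, x$seed))
  print(x$table, row.names = FALSE)
  cat("Chosen:", x$chosen_family, "\n")
  if (length(x$flags)) cat(length(x$flags), "fold-level flags\n")
  invisible(x)
}

#' The two cooperation regressions
#'
#' Convenience wrapper fitting the trait-only and the full covariate set
#' for a dependent variable, mirroring the main coefficient table: traits
#' only (partialling check), then gender, maximise, traits, the feedback
#' factorial with its interaction, and game version.
#'
#' @param data participant-summary data frame.
#' @param response `"cooperation"`, `"cac"` or `"cad"`.
#' @param family model family (the cross-validated winner; Gaussian by
#'   default).
#' @return List with elements `traits_only` and `full`, both `ipd_fit`.
#' @export
cooperation_regressions <- function(data, response = "cooperation",
                                    family = "gaussian_identity") {
  list(
    traits_only = fit_model(model_spec(family, response, trait_terms()), data),
    full = fit_model(model_spec(family, response, full_terms()), data)
  )
}

#' Separate psychopathy-interaction regressions
#'
#' Four fits per dependent variable, each adding one interaction between
#' the aggregate psychopathy score and a design variable (game version;
#' positive x negative feedback; positive feedback; negative feedback) to
#' a control set of gender, game version, maximise, narcissism and the
#' condition dummies. Lower-order terms of each interaction are included;
#' the focal row reported is the highest-order interaction.
#'
#' @param data participant-summary data frame with a
#'   `sum_psychopathic_traits` column.
#' @param responses dependent variables to run.
#' @param family model family.
#' @return Data frame: response, interaction, estimate, se, p, stars,
#'   flagged (TRUE when the term was dropped for collinearity).
#' @export
interaction_regressions <- function(data, responses = c("cooperation", "cac"),
                                    family = "gaussian_identity") {
  abort_if(!"sum_psychopathic_traits" %in% names(data),
           "data must carry sum_psychopathic_traits")
  controls <- c("gender", "game_version", "maximise", "narcissism",
                "positive_feedback", "negative_feedback",
                "positive_feedback:negative_feedback")
  interactions <- list(
    "game_version:sum_psychopathic_traits" =
      c("sum_psychopathic_traits", "game_version:sum_psychopathic_traits"),
    "positive_feedback:negative_feedback:sum_psychopathic_traits" =
      c("sum_psychopathic_traits",
        "positive_feedback:sum_psychopathic_traits",
        "negative_feedback:sum_psychopathic_traits",
        "positive_feedback:negative_feedback:sum_psychopathic_traits"),
    "positive_feedback:sum_psychopathic_traits" =
      c("sum_psychopathic_traits", "positive_feedback:sum_psychopathic_traits"),
    "negative_feedback:sum_psychopathic_traits" =
      c("sum_psychopathic_traits", "negative_feedback:sum_psychopathic_traits")
  )
  out <- list()
  for (resp in responses) {
    for (nm in names(interactions)) {
      spec <- model_spec(family, resp, c(controls, interactions[[nm]]))
      fit <- fit_model(spec, data)
      cf <- fit$coefficients
      focal <- cf[cf$term == nm, , drop = FALSE]
      flagged <- nrow(focal) == 0 || is.na(focal$estimate[1]) ||
        is.na(focal$se[1])
      out[[length(out) + 1L]] <- data.frame(
        response = resp, interaction = nm,
        estimate = if (nrow(focal)) focal$estimate[1] else NA_real_,
        se = if (nrow(focal)) focal$se[1] else NA_real_,
        p = if (nrow(focal)) focal$p[1] else NA_real_,
        stars = if (nrow(focal)) focal$stars[1] else "",
        flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
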