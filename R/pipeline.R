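#' Run configuration for the full pipeline
#'
#' Either point `rounds_csv`/`participants_csv` at experimental data in the
#' documented schemas, or leave them `NULL` to analyse a synthetic cohort
#' generated from `cohort` at the run seed.
#'
#' @param cohort an [cohort_spec()] used when no input paths are given.
#' @param rounds_csv,participants_csv optional paths to round-level and
#'   participant-level CSVs.
#' @param strategy_preset strategy set for the inference stage
#'   (`"table6"`, `"full"`, or a character vector of abbreviations).
#' @param dv_normalization CaC normalisation handed to the regressions
#'   (see [participant_summaries()]).
#' @param cv_k,cv_repeats cross-validation folds and repeats.
#' @param bootstrap_B bootstrap replicates for the frequency SEs.
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir optional output directory; when given, all tables, the
#'   rendered text report and a manifest JSON are written there.
#' @return An object of class `ipd_run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), rounds_csv = NULL,
                       participants_csv = NULL,
                       strategy_preset = "table6",
                       dv_normalization = c("total", "conditional"),
                       cv_k = 5L, cv_repeats = 10L,
                       bootstrap_B = 1000L, seed = 1L, out_dir = NULL) {
  dv_normalization <- match.arg(dv_normalization)
  for (p in c(rounds_csv, participants_csv)) {
    abort_if(!file.exists(p), sprintf("input file does not exist: %s", p))
  }
  structure(list(cohort = cohort, rounds_csv = rounds_csv,
                 participants_csv = participants_csv,
                 strategy_preset = strategy_preset,
                 dv_normalization = dv_normalization,
                 cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "ipd_run_config")
}

#' Validate input tables
#'
#' Schema and content checks for the round-level and participant-level
#' tables: required columns, action symbols, per-participant round
#' completeness, condition and coding ranges. Fatal problems (unknown
#' action symbols, invalid codes, missing columns) are collected in
#' `$fatal`; non-fatal issues (e.g. a participant with fewer rounds than
#' the horizon, unbalanced conditions) in `$warnings`.
#'
#' @param rounds round-level data frame.
#' @param participants optional participant-level data frame.
#' @param rounds_total expected horizon.
#' @return A list with `fatal`, `warnings` and `ok` (no fatal issues).
#' @export
validate_input <- function(rounds, participants = NULL, rounds_total = 30L) {
  fatal <- character(0)
  warn <- character(0)
  need <- c("participant_id", "round", "participant_action", "computer_action")
  miss <- setdiff(need, names(rounds))
  if (length(miss)) {
    fatal <- c(fatal, paste("rounds table missing columns:",
                            paste(miss, collapse = ", ")))
  } else {
    for (col in c("participant_action", "computer_action")) {
      bad <- setdiff(unique(rounds[[col]]), c("C", "D"))
      if (length(bad)) {
        fatal <- c(fatal, sprintf("invalid action symbol(s) in %s: %s",
                                  col, paste(bad, collapse = ", ")))
      }
    }
    counts <- table(rounds$participant_id)
    short <- names(counts)[counts != rounds_total]
    if (length(short)) {
      warn <- c(warn, sprintf("participant(s) without %d rounds: %s",
                              rounds_total, paste(short, collapse = ", ")))
    }
    if ("condition" %in% names(rounds)) {
      badc <- setdiff(unique(rounds$condition), 1:4)
      if (length(badc)) {
        fatal <- c(fatal, paste("invalid condition id(s):",
                                paste(badc, collapse = ", ")))
      }
    }
  }
  if (!is.null(participants)) {
    if ("gender" %in% names(participants)) {
      badg <- setdiff(unique(participants$gender), c(1L, 2L))
      if (length(badg)) {
        fatal <- c(fatal, paste("gender codes must be 1 (female) or 2 (male); found:",
                                paste(badg, collapse = ", ")))
      }
    }
    if ("game_version" %in% names(participants)) {
      badv <- setdiff(unique(participants$game_version), c(1L, 2L))
      if (length(badv)) {
        fatal <- c(fatal, paste("game_version must be 1 or 2; found:",
                                paste(badv, collapse = ", ")))
      }
    }
    if ("condition" %in% names(participants)) {
      tab <- table(participants$condition)
      if (length(unique(tab)) > 1) {
        warn <- c(warn, "condition cell counts are unbalanced")
      }
    }
  }
  list(fatal = fatal, warnings = warn, ok = length(fatal) == 0)
}

stage_msg <- function(quiet, ...) if (!quiet) message("[ipdstrat] ", sprintf(...))

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, exclusion, behavioural metrics, model
#' selection, the cooperation and interaction regressions, and strategy
#' inference with bootstrap SEs, trait correlations and the SFEM
#' population cross-check. With `out_dir` set in the config, writes every
#' table (CSV/JSON), a plain-text report and a manifest recording seeds
#' and row counts.
#'
#' @param config an [run_config()].
#' @param quiet suppress stage messages.
#' @return A list of class `ipd_run` with elements `participants`,
#'   `rounds`, `summaries`, `correlations`, `cv`, `regressions`,
#'   `interactions`, `strategy` (fits, estimate, trait_correlations, sfem)
#'   and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  abort_if(!inherits(config, "ipd_run_config"), "config must be an ipd_run_config")
  seed <- config$seed
  warnings_log <- character(0)

  # --- stage 1: ingest or simulate -----------------------------------------
  if (!is.null(config$rounds_csv)) {
    stage_msg(quiet, "ingest: reading %s", config$rounds_csv)
    rounds <- utils::read.csv(config$rounds_csv, stringsAsFactors = FALSE)
    participants <- if (!is.null(config$participants_csv)) {
      utils::read.csv(config$participants_csv, stringsAsFactors = FALSE)
    } else NULL
    rt <- if (nrow(rounds)) max(table(rounds$participant_id)) else
      config$cohort$rounds_total
    val <- validate_input(rounds, participants, rounds_total = rt)
    abort_if(!val$ok, paste("ingest: fatal validation errors:\n ",
                            paste(val$fatal, collapse = "\n  ")))
    warnings_log <- c(warnings_log, val$warnings)
  } else {
    stage_msg(quiet, "simulate: generating synthetic cohort (n = %d, seed = %d)",
              config$cohort$n_participants, seed)
    cohort <- generate_cohort(config$cohort, seed = seed)
    rounds <- cohort$rounds
    participants <- cohort$participants
  }
  n_in <- length(unique(rounds$participant_id))

  # --- stage 2: exclusion ---------------------------------------------------
  if (!is.null(participants) && "irs10" %in% names(participants)) {
    excl <- apply_irs_exclusion(participants$irs10)
    if (excl$n_excluded > 0) {
      keep_ids <- participants$participant_id[excl$retained]
      participants <- participants[excl$retained, , drop = FALSE]
      rounds <- rounds[rounds$participant_id %in% keep_ids, , drop = FALSE]
    }
    stage_msg(quiet, "exclude: %d of %d retained (IRS-10 >= 13 removed: %d)",
              excl$n_retained, n_in, excl$n_excluded)
  }

  # --- stage 3: behavioural metrics ----------------------------------------
  summaries <- participant_summaries(rounds, participants,
                                     normalization = config$dv_normalization)
  cor_vars <- intersect(
    c("cooperation", "cac", "sum_psychopathic_traits",
      "self_centred_impulsivity", "fearless_dominance", "coldheartedness",
      "narcissism", "maximise"),
    names(summaries))
  correlations <- correlation_matrix(summaries, cor_vars)
  stage_msg(quiet, "metrics: %d participant summaries", nrow(summaries))

  # --- stage 4: model selection --------------------------------------------
  regress_ok <- all(c("gender", "maximise", "fearless_dominance",
                      "narcissism", "positive_feedback", "negative_feedback",
                      "game_version") %in% names(summaries))
  cv <- NULL; regressions <- NULL; interactions <- NULL
  if (regress_ok) {
    cv <- lapply(c(cooperation = "cooperation", cac = "cac"), function(dv) {
      specs <- lapply(c("gaussian_identity", "binomial_logit", "beta_binomial"),
                      model_spec, response = dv, terms = full_terms())
      cv_select(specs, summaries, k = config$cv_k,
                repeats = config$cv_repeats, seed = seed + 1L)
    })
    chosen <- vapply(cv, `[[`, character(1), "chosen_family")
    stage_msg(quiet, "cv_select: chose %s (cooperation), %s (CaC)",
              chosen[["cooperation"]], chosen[["cac"]])

    # --- stage 5: regressions ----------------------------------------------
    regressions <- lapply(c(cooperation = "cooperation", cac = "cac"),
                          function(dv) {
      cooperation_regressions(summaries, response = dv,
                              family = cv[[dv]]$chosen_family)
    })
    interactions <- if ("sum_psychopathic_traits" %in% names(summaries)) {
      interaction_regressions(summaries,
                              family = cv[["cooperation"]]$chosen_family)
    } else NULL
    stage_msg(quiet, "regress: trait-only + full fits for both DVs, %d interaction fits",
              if (is.null(interactions)) 0L else nrow(interactions))
  } else {
    warnings_log <- c(warnings_log,
                      "regression stage skipped: covariate columns missing")
  }

  # --- stage 6: strategy inference -----------------------------------------
  strategy_set <- build_strategy_set(config$strategy_preset)
  fits <- fit_cohort(rounds, strategy_set)
  estimate <- strategy_estimates(rounds, strategy_set, estimator = "sfem",
                                 B = config$bootstrap_B, seed = seed + 2L)
  subject_avg <- cohort_estimates(fits)
  sfem <- estimate$sfem
  trait_cors <- if (!is.null(participants) &&
                    all(c("fearless_dominance", "self_centred_impulsivity",
                          "coldheartedness") %in% names(participants))) {
    ord <- match(rownames(sfem$posterior),
                 as.character(participants$participant_id))
    trait_strategy_correlations(sfem$posterior,
                                participants[ord, , drop = FALSE])
  } else NULL
  if (any(fits$degenerate)) {
    warnings_log <- c(warnings_log, sprintf(
      "%d participant fit(s) degenerate (all likelihoods zero)",
      sum(fits$degenerate)))
  }
  stage_msg(quiet, "infer-strategies: %d participants x %d strategies, gamma = %.2f",
            nrow(fits$weights), length(strategy_set), estimate$gamma)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ipdstrat")),
    seed = seed,
    stage_seeds = list(cv = seed + 1L, bootstrap = seed + 2L, sfem = seed + 3L),
    strategy_preset = config$strategy_preset,
    dv_normalization = config$dv_normalization,
    n_participants_in = n_in,
    n_participants_analysed = nrow(summaries),
    n_rounds = nrow(rounds),
    cv = list(k = config$cv_k, repeats = config$cv_repeats),
    bootstrap_B = config$bootstrap_B,
    warnings = warnings_log
  )

  run <- structure(list(participants = participants, rounds = rounds,
                        summaries = summaries, correlations = correlations,
                        cv = cv, regressions = regressions,
                        interactions = interactions,
                        strategy = list(fits = fits, estimate = estimate,
                                        subject_average = subject_avg,
                                        trait_correlations = trait_cors,
                                        sfem = sfem),
                        manifest = manifest),
                   class = "ipd_run")
  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
    stage_msg(quiet, "report: written to %s", config$out_dir)
  }
  run
}

#' Write a pipeline run to disk
#'
#' Emits tidy CSVs for rounds, participants and summaries, the correlation
#' matrix, the regression and interaction coefficient tables, the strategy
#' estimates (JSON plus a rendered text table) and the manifest JSON.
#'
#' @param run an `ipd_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wcsv(run$rounds, "rounds.csv")
  if (!is.null(run$participants)) wcsv(run$participants, "participants.csv")
  wcsv(run$summaries, "participant_summaries.csv")
  wcsv(as.data.frame(run$correlations$r), "correlation_matrix.csv")

  if (!is.null(run$regressions)) {
    coef_rows <- do.call(rbind, unlist(lapply(names(run$regressions), function(dv) {
      lapply(names(run$regressions[[dv]]), function(kind) {
        cf <- run$regressions[[dv]][[kind]]$coefficients
        cbind(data.frame(response = dv, model = kind), cf)
      })
    }), recursive = FALSE))
    wcsv(coef_rows, "regression_coefficients.csv")
  }
  if (!is.null(run$interactions)) wcsv(run$interactions, "interaction_coefficients.csv")
  if (!is.null(run$cv)) {
    cv_rows <- do.call(rbind, lapply(names(run$cv), function(dv) {
      cbind(data.frame(dv = dv), run$cv[[dv]]$table,
            chosen = run$cv[[dv]]$chosen_family)
    }))
    wcsv(cv_rows, "cv_selection.csv")
  }

  est <- run$strategy$estimate
  est_path <- file.path(dir, "strategy_estimates.json")
  jsonlite::write_json(list(estimator = est$estimator,
                            frequencies = as.list(est$frequencies),
                            se = as.list(est$se), p = as.list(est$p),
                            gamma = est$gamma, gamma_se = est$gamma_se,
                            n = est$n, B = est$B, seed = est$seed,
                            subject_average = list(
                              frequencies = as.list(run$strategy$subject_average$frequencies),
                              gamma = run$strategy$subject_average$gamma)),
                       est_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, est_path)

  txt_path <- file.path(dir, "strategy_table.txt")
  con <- file(txt_path, "w")
  sink(con)
  print(est)
  if (!is.null(run$strategy$trait_correlations)) {
    cat("\nCorrelations between strategy weights and psychopathy factors\n")
    print(run$strategy$trait_correlations)
  }
  sink()
  close(con)
  files <- c(files, txt_path)

  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, man_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, man_path)
  invisible(files)
}

#' @export
print.ipd_run <- function(x, ...) {
  cat(sprintf("<ipd_run: %d participants analysed, %d rounds>\n",
              x$manifest$n_participants_analysed, x$manifest$n_rounds))
  if (!is.null(x$cv)) {
    cat("CV winners:",
        paste(vapply(x$cv, `[[`, character(1), "chosen_family"), collapse = ", "),
        "\n")
  }
  print(x$strategy$estimate)
  invisible(x)
}
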