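#' Overall cooperation rate
#'
#' Fraction of rounds in which the player cooperated.
#'
#' @param choices character vector of `"C"`/`"D"` actions.
#' @return Numeric fraction in `[0, 1]`.
#' @export
overall_cooperation <- function(choices) {
  choices <- as_actions(choices)
  abort_if(length(choices) == 0, "choices must be non-empty")
  mean(choices == "C")
}

#' Cooperation following one's own cooperation (CaC)
#'
#' Number of rounds `t >= 2` in which the player cooperated and had also
#' cooperated at `t - 1`. Conditioning is on the player's *own* previous
#' action: the count measures persistence of cooperative behaviour.
#'
#' @param choices character vector of actions, length >= 2.
#' @return Non-negative integer count.
#' @export
cac_count <- function(choices) {
  choices <- as_actions(choices)
  abort_if(length(choices) < 2, "need at least two rounds")
  T <- length(choices)
  sum(choices[-T] == "C" & choices[-1] == "C")
}

#' Cooperation following one's own defection (CaD)
#'
#' @inheritParams cac_count
#' @return Non-negative integer count of rounds where the player cooperated
#'   immediately after defecting.
#' @export
cad_count <- function(choices) {
  choices <- as_actions(choices)
  abort_if(length(choices) < 2, "need at least two rounds")
  T <- length(choices)
  sum(choices[-T] == "D" & choices[-1] == "C")
}

#' Cooperation following the opponent's cooperation
#'
#' Sensitivity-analysis variant of [cac_count()] that conditions on the
#' opponent's previous action instead of the player's own.
#'
#' @param choices player's actions, length >= 2.
#' @param opponent opponent's actions, same length.
#' @return Non-negative integer count.
#' @export
cac_count_opponent <- function(choices, opponent) {
  choices <- as_actions(choices)
  opponent <- as_actions(opponent, "opponent")
  abort_if(length(choices) != length(opponent), "sequences must match in length")
  abort_if(length(choices) < 2, "need at least two rounds")
  T <- length(choices)
  sum(opponent[-T] == "C" & choices[-1] == "C")
}

#' Per-participant behavioural summaries
#'
#' Collapses round-level records to one row per participant: overall
#' cooperation, CaC and CaD counts and their normalised versions, joined
#' with whatever participant-level columns are supplied.
#'
#' @param rounds round-level data frame with columns `participant_id`,
#'   `round`, `participant_action` (and optionally `computer_action`).
#' @param participants optional participant-level data frame with a
#'   `participant_id` column to join on.
#' @param normalization `"total"` divides the CaC count by `rounds - 1`
#'   (commensurate with overall cooperation); `"conditional"` divides by
#'   the number of own previous cooperations (NA when the player never
#'   cooperated before the last round).
#' @return Data frame, one row per participant, with a `cac_normalization`
#'   attribute recording the choice.
#' @export
participant_summaries <- function(rounds, participants = NULL,
                                  normalization = c("total", "conditional")) {
  normalization <- match.arg(normalization)
  need <- c("participant_id", "round", "participant_action")
  abort_if(!all(need %in% names(rounds)),
           "rounds must have participant_id, round, participant_action")
  ord <- order(rounds$participant_id, rounds$round)
  rounds <- rounds[ord, ]
  by_p <- split(rounds, rounds$participant_id)
  rows <- lapply(by_p, function(d) {
    ch <- d$participant_action
    T <- length(ch)
    cac <- cac_count(ch)
    prev_coop <- sum(ch[-T] == "C")
    data.frame(
      participant_id = d$participant_id[1],
      rounds_played = T,
      cooperation = overall_cooperation(ch),
      cac_count = cac,
      cad_count = cad_count(ch),
      cac = if (normalization == "total") cac / (T - 1) else
        if (prev_coop > 0) cac / prev_coop else NA_real_,
      cad = cad_count(ch) / (T - 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(participants)) {
    out <- merge(out, participants, by = "participant_id", sort = TRUE)
  }
  attr(out, "cac_normalization") <- normalization
  out
}

#' Bivariate correlation matrix with significance stars
#'
#' Pearson correlations among the named columns, with two-sided p-values
#' from [stats::cor.test()] mapped to stars ('***' < 0.001, '**' < 0.01,
#' '*' < 0.05, '.' < 0.1). Constant variables are flagged and their
#' correlations left `NA`.
#'
#' @param data data frame of numeric columns.
#' @param variables column names to correlate, in display order.
#' @return A list of class `ipd_cormat` with matrices `r`, `p`, `stars`
#'   and a character vector `constant` naming degenerate variables.
#' @export
correlation_matrix <- function(data, variables = names(data)) {
  abort_if(nrow(data) < 3, "need at least three observations")
  missing_vars <- setdiff(variables, names(data))
  abort_if(length(missing_vars) > 0, sprintf(
    "variables not in data: %s", paste(missing_vars, collapse = ", ")))
  X <- data[variables]
  constant <- variables[vapply(X, function(x) stats::sd(x) == 0, logical(1))]
  k <- length(variables)
  r <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- r
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    if (variables[i] %in% constant || variables[j] %in% constant) next
    ct <- stats::cor.test(X[[i]], X[[j]])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix(p_stars(p), k, k, dimnames = dimnames(r))
  structure(list(r = r, p = p, stars = stars, constant = constant, n = nrow(data)),
            class = "ipd_cormat")
}

#' @export
print.ipd_cormat <- function(x, digits = 2, ...) {
  k <- ncol(x$r)
  vars <- colnames(x$r)
  cells <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) { cells[i, j] <- "-"; next }
    if (is.na(x$r[i, j])) { cells[i, j] <- "NA"; next }
    cells[i, j] <- paste0(formatC(x$r[i, j], digits = digits, format = "f"),
                          x$stars[i, j])
  }
  print(as.data.frame(cells), right = TRUE)
  cat("Significance: '***' < 0.001 '**' < 0.01 '*' < 0.05 '.' < 0.1\n")
  if (length(x$constant)) {
    cat("Constant (correlation undefined):",
        paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}
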