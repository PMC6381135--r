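#' Construct a joint history
#'
#' A joint history records, round by round, the paired actions of a player
#' and their opponent. It is the information set on which both the strategy
#' automata and the tremble likelihood condition. Round indexing is 1-based.
#'
#' @param own character vector of the player's actions (`"C"`/`"D"`).
#' @param opp character vector of the opponent's actions, same length.
#' @param rounds_total horizon of the game (default 30).
#' @return An object of class `ipd_history`.
#' @examples
#' joint_history(c("C", "D"), c("C", "C"))
#' @export
joint_history <- function(own = character(), opp = character(), rounds_total = 30L) {
  own <- as_actions(own, "own actions")
  opp <- as_actions(opp, "opponent actions")
  abort_if(length(own) != length(opp),
           "own and opponent action sequences must have equal length")
  rounds_total <- as.integer(rounds_total)
  abort_if(rounds_total < 1L, "rounds_total must be a positive integer")
  abort_if(length(own) > rounds_total,
           "history is longer than the game horizon")
  structure(list(own = own, opp = opp, rounds_total = rounds_total),
            class = "ipd_history")
}

#' @export
print.ipd_history <- function(x, ...) {
  cat(sprintf("<ipd_history: %d of %d rounds>\n", length(x$own), x$rounds_total))
  if (length(x$own)) {
    cat(" own:", paste(x$own, collapse = ""), "\n")
    cat(" opp:", paste(x$opp, collapse = ""), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Catalogue
#
# Every deterministic strategy used here is a member of one trigger/release
# automaton family plus the two constant strategies. A strategy is content
# (cooperate) until the opponent defects `trigger` times in a row, then
# punishes (defect) until released:
#   one_coop — a single opponent cooperation ends the punishment,
#   two_coop — the opponent must cooperate twice in a row,
#   never    — the punishment is permanent (Grim triggers).
# Tit-for-tat is trigger 1 / one_coop; "two tits for a tat" (defect for the
# two rounds following any opponent defection) is exactly trigger 1 /
# two_coop. Strategies condition on the opponent's actions only.
# ---------------------------------------------------------------------------

.catalogue <- list(
  list(abbr = "ALLC",  name = "Always cooperate", first = "C", always = "C",
       trigger = Inf, release = "none", memory = 0,
       description = "Cooperate at each round"),
  list(abbr = "ALLD",  name = "Always defect", first = "D", always = "D",
       trigger = Inf, release = "none", memory = 0,
       description = "Defect at each round"),
  list(abbr = "TFT",   name = "Tit for tat", first = "C", always = NA,
       trigger = 1, release = "one_coop", memory = 1,
       description = "Cooperate first, then copy the opponent's last move"),
  list(abbr = "TF2T",  name = "Tit for two tats", first = "C", always = NA,
       trigger = 2, release = "one_coop", memory = 2,
       description = paste("Cooperate until the opponent defects twice in a",
                           "row, then defect till the opponent cooperates again")),
  list(abbr = "TF3T",  name = "Tit for three tats", first = "C", always = NA,
       trigger = 3, release = "one_coop", memory = 3,
       description = paste("Cooperate until the opponent defects three times",
                           "in a row, then defect till the opponent cooperates again")),
  list(abbr = "2TFT",  name = "Two tits for a tat", first = "C", always = NA,
       trigger = 1, release = "two_coop", memory = 2,
       description = paste("Cooperate unless the opponent defected in either",
                           "of the last two rounds")),
  list(abbr = "2TF2T", name = "Two tits for two tats", first = "C", always = NA,
       trigger = 2, release = "two_coop", memory = Inf,
       description = paste("Cooperate until the opponent defects twice in a",
                           "row, then defect till the opponent cooperates twice in a row")),
  list(abbr = "Grim",  name = "Grim trigger", first = "C", always = NA,
       trigger = 1, release = "never", memory = Inf,
       description = "Cooperate until the opponent defects, then defect forever"),
  list(abbr = "Grim2", name = "Grim trigger (two defections)", first = "C", always = NA,
       trigger = 2, release = "never", memory = Inf,
       description = paste("Cooperate until the opponent defects twice in a",
                           "row, then defect forever")),
  list(abbr = "Grim3", name = "Grim trigger (three defections)", first = "C", always = NA,
       trigger = 3, release = "never", memory = Inf,
       description = paste("Cooperate until the opponent defects three times",
                           "in a row, then defect forever")),
  list(abbr = "DTFT",  name = "Suspicious tit for tat", first = "D", always = NA,
       trigger = 1, release = "one_coop", memory = 1,
       description = "Defect in the first round, then play tit for tat")
)
names(.catalogue) <- vapply(.catalogue, `[[`, character(1), "abbr")

# Named presets; "table6" is the four-strategy set used for the headline
# frequency table, in its column order.
.presets <- list(
  table6 = c("TF3T", "2TF2T", "Grim", "ALLD"),
  full   = names(.catalogue)
)

#' Build a set of strategy automata
#'
#' @param names character vector of catalogue abbreviations, or a preset name
#'   (`"table6"` for the four headline strategies TF3T, 2TF2T, Grim, ALLD;
#'   `"full"` for the whole catalogue).
#' @return A named list of `ipd_strategy` objects in the requested order.
#' @examples
#' build_strategy_set(c("TFT", "ALLD"))
#' build_strategy_set("table6")
#' @export
build_strategy_set <- function(names = "full") {
  if (length(names) == 1 && names %in% base::names(.presets)) {
    names <- .presets[[names]]
  }
  abort_if(anyDuplicated(names) > 0, "duplicate strategy abbreviation in set")
  unknown <- setdiff(names, base::names(.catalogue))
  abort_if(length(unknown) > 0, sprintf(
    "unknown strategy abbreviation(s): %s. Valid names: %s",
    paste(unknown, collapse = ", "),
    paste(base::names(.catalogue), collapse = ", ")
  ))
  out <- lapply(.catalogue[names], function(e) structure(e, class = "ipd_strategy"))
  names(out) <- names
  out
}

#' @export
print.ipd_strategy <- function(x, ...) {
  cat(sprintf("<ipd_strategy %s (%s): %s>\n", x$abbr, x$name, x$description))
  invisible(x)
}

# Advance the punishment state of a trigger/release automaton after
# observing one opponent move. Vectorised over participants: `trigger` and
# `release_two`/`release_never` may be vectors. State components:
#   run_d — current streak of opponent defections
#   run_c — current streak of opponent cooperations
#   punish — 1 while in the punishment phase
automaton_step <- function(state, opp_move, trigger, release) {
  d <- opp_move == "D"
  run_d <- ifelse(d, state$run_d + 1L, 0L)
  run_c <- ifelse(d, 0L, state$run_c + 1L)
  triggered <- run_d >= trigger
  released <- !d & state$punish == 1L &
    ((release == "one_coop") | (release == "two_coop" & run_c >= 2L))
  punish <- as.integer((state$punish == 1L | triggered) & !released)
  list(run_d = as.integer(run_d), run_c = as.integer(run_c), punish = punish)
}

automaton_init <- function(n = 1L) {
  list(run_d = integer(n), run_c = integer(n), punish = integer(n))
}

#' Action a strategy prescribes after a history
#'
#' Replays the automaton over the opponent's realised actions and returns
#' the action prescribed for the next round. The prescription is a pure,
#' deterministic function of the history, so a player who trembled earlier
#' is still scored against what the strategy would do given what actually
#' happened.
#'
#' @param strategy an `ipd_strategy` from [build_strategy_set()].
#' @param history an [joint_history()] of the rounds played so far (the
#'   strategy reads the `opp` side).
#' @return `"C"` or `"D"`.
#' @examples
#' grim <- build_strategy_set("Grim")[[1]]
#' prescribe(grim, joint_history(c("C", "C"), c("C", "D")))
#' @export
prescribe <- function(strategy, history) {
  abort_if(!inherits(strategy, "ipd_strategy"), "strategy must be an ipd_strategy")
  abort_if(!inherits(history, "ipd_history"), "history must be an ipd_history")
  if (!is.na(strategy$always)) return(strategy$always)
  t_next <- length(history$opp) + 1L
  if (t_next == 1L) return(strategy$first)
  st <- automaton_init(1L)
  for (o in history$opp) {
    st <- automaton_step(st, o, strategy$trigger, strategy$release)
  }
  if (st$punish == 1L) "D" else "C"
}

#' Round-by-round prescriptions along a realised history
#'
#' Element `t` is the action the strategy prescribes for round `t` given the
#' history truncated to rounds `1..t-1`. This is the sequence the tremble
#' likelihood compares a player's realised choices against.
#'
#' @inheritParams prescribe
#' @return Character vector of length `length(history$own)`.
#' @export
prescribed_sequence <- function(strategy, history) {
  abort_if(!inherits(strategy, "ipd_strategy"), "strategy must be an ipd_strategy")
  abort_if(!inherits(history, "ipd_history"), "history must be an ipd_history")
  T <- length(history$opp)
  if (!is.na(strategy$always)) return(rep(strategy$always, T))
  if (T == 0L) return(character())
  out <- character(T)
  out[1] <- strategy$first
  st <- automaton_init(1L)
  if (T > 1L) {
    for (t in 2:T) {
      st <- automaton_step(st, history$opp[t - 1L], strategy$trigger, strategy$release)
      out[t] <- if (st$punish == 1L) "D" else "C"
    }
  }
  out
}

#' The strategy catalogue as a table
#'
#' @param json if `TRUE`, return the machine-readable registry as a JSON
#'   string instead of a data frame.
#' @return A data frame (or JSON string) with one row per catalogued
#'   strategy: abbreviation, name, description, trigger length, release
#'   rule, first move and memory depth (`Inf` = unbounded).
#' @export
strategy_catalogue <- function(json = FALSE) {
  df <- do.call(rbind, lapply(.catalogue, function(e) {
    data.frame(abbr = e$abbr, name = e$name, description = e$description,
               first_move = e$first,
               constant = ifelse(is.na(e$always), "", e$always),
               trigger = e$trigger, release = e$release, memory = e$memory,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (json) {
    return(jsonlite::toJSON(df, auto_unbox = TRUE, pretty = TRUE, digits = NA))
  }
  df
}

#' @rdname strategy_catalogue
#' @export
strategy_presets <- function() .presets
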