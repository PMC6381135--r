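#' Payoff matrix for the pricing game
#'
#' Payoffs are percentage profits in the shop cover story: both keep the
#' standard price (mutual cooperation) and each earns `reward`; both go on
#' sale (mutual defection) and each earns `punishment`; undercutting a
#' cooperating opponent earns the `temptation` payoff and leaves the
#' cooperator the `sucker` payoff. The defaults are the experiment's 30/20/
#' 40/10 cells and must respect the Prisoner's Dilemma ordering T > R > P > S.
#'
#' @param reward,punishment,temptation,sucker percentage payoffs.
#' @return An object of class `ipd_payoff`.
#' @export
payoff_matrix <- function(reward = 30, punishment = 20, temptation = 40, sucker = 10) {
  abort_if(!(temptation > reward && reward > punishment && punishment > sucker),
           "payoffs must satisfy the Prisoner's Dilemma ordering T > R > P > S")
  structure(list(R = reward, P = punishment, T = temptation, S = sucker),
            class = "ipd_payoff")
}

#' Payoffs for one round
#'
#' @param own,opp actions (`"C"`/`"D"`), vectorised.
#' @param matrix an [payoff_matrix()].
#' @return A list with numeric vectors `own` and `opp` of percentage payoffs.
#' @examples
#' payoff("D", "C")  # temptation vs sucker: 40 vs 10
#' @export
payoff <- function(own, opp, matrix = payoff_matrix()) {
  own <- as_actions(own, "own action")
  opp <- as_actions(opp, "opponent action")
  pick <- function(a, b) {
    ifelse(a == "C" & b == "C", matrix$R,
    ifelse(a == "D" & b == "D", matrix$P,
    ifelse(a == "D" & b == "C", matrix$T, matrix$S)))
  }
  list(own = pick(own, opp), opp = pick(opp, own))
}

#' Experimental condition
#'
#' The four between-subject conditions form a 2x2 factorial in the presence
#' of positive feedback (a happy face after cooperation) and negative
#' feedback (a sad face after defection): condition 1 = neither, 2 =
#' negative only, 3 = positive only, 4 = both.
#'
#' @param id integer 1-4.
#' @return A list with `id`, `positive_feedback` and `negative_feedback`.
#' @export
condition <- function(id) {
  id <- as.integer(id)
  abort_if(!id %in% 1:4, "condition id must be 1, 2, 3 or 4")
  list(id = id,
       positive_feedback = as.integer(id %in% c(3L, 4L)),
       negative_feedback = as.integer(id %in% c(2L, 4L)))
}

#' Emotional feedback label shown after a decision
#'
#' Cooperation is answered with a happy face when the condition includes
#' positive feedback, otherwise a neutral one; defection with a sad face
#' when the condition includes negative feedback, otherwise neutral.
#'
#' @param action the participant's action, vectorised.
#' @param cond a [condition()].
#' @return `"happy"`, `"neutral"` or `"sad"`.
#' @export
feedback_label <- function(action, cond) {
  action <- as_actions(action)
  ifelse(action == "C",
         ifelse(cond$positive_feedback == 1L, "happy", "neutral"),
         ifelse(cond$negative_feedback == 1L, "sad", "neutral"))
}

#' Game configuration
#'
#' @param rounds_total number of rounds (30 in the experiment).
#' @param endgame_defect_rounds number of final rounds in which the computer
#'   defects unconditionally (2 in the experiment).
#' @param game_version 1 = deception arm (participants told the opponent is
#'   human), 2 = non-deception arm.
#' @param cond a [condition()].
#' @param matrix a [payoff_matrix()].
#' @return An object of class `ipd_config`.
#' @export
game_config <- function(rounds_total = 30L, endgame_defect_rounds = 2L,
                        game_version = 1L, cond = condition(1L),
                        matrix = payoff_matrix()) {
  rounds_total <- as.integer(rounds_total)
  endgame_defect_rounds <- as.integer(endgame_defect_rounds)
  abort_if(rounds_total < 1L, "rounds_total must be positive")
  abort_if(endgame_defect_rounds < 0L || endgame_defect_rounds >= rounds_total,
           "endgame_defect_rounds must be non-negative and below rounds_total")
  abort_if(!game_version %in% c(1L, 2L), "game_version must be 1 or 2")
  structure(list(rounds_total = rounds_total,
                 endgame_defect_rounds = endgame_defect_rounds,
                 game_version = as.integer(game_version),
                 cond = cond, matrix = matrix),
            class = "ipd_config")
}

#' The scripted computer opponent's move
#'
#' The computer plays tit-for-two-tats: it cooperates until the participant
#' defects twice in a row, then defects until the participant cooperates
#' again (a single cooperation ends the punishment). In the final
#' `endgame_defect_rounds` rounds it defects regardless of the history.
#'
#' @param history an [joint_history()] whose `own` side is the participant;
#'   must cover rounds `1..round-1`.
#' @param round the round about to be played (1-based).
#' @param config an [game_config()].
#' @return `"C"` or `"D"`.
#' @export
computer_move <- function(history, round, config = game_config()) {
  abort_if(!inherits(history, "ipd_history"), "history must be an ipd_history")
  round <- as.integer(round)
  abort_if(round < 1L || round > config$rounds_total,
           "round outside the game horizon")
  abort_if(length(history$own) != round - 1L,
           "history length inconsistent with round number")
  if (round > config$rounds_total - config$endgame_defect_rounds) return("D")
  if (round == 1L) return("C")
  st <- automaton_init(1L)
  for (a in history$own) st <- automaton_step(st, a, 2L, "one_coop")
  if (st$punish == 1L) "D" else "C"
}

#' Play one session against the computer
#'
#' Runs a full game: each round the participant policy is consulted on the
#' realised joint history, the computer answers with its tit-for-two-tats
#' rule (with endgame defection), and payoffs plus the condition's feedback
#' label are recorded.
#'
#' @param policy a function `(ipd_history) -> "C"/"D"` giving the
#'   participant's action for the next round; e.g. a wrapped
#'   [prescribe()] or a stochastic policy.
#' @param config an [game_config()].
#' @return A data frame with one row per round: `round`,
#'   `participant_action`, `computer_action`, `participant_payoff`,
#'   `computer_payoff`, `feedback`.
#' @examples
#' allc <- build_strategy_set("ALLC")[[1]]
#' sess <- play_session(function(h) prescribe(allc, h))
#' table(sess$computer_action)  # D in the two endgame rounds only
#' @export
play_session <- function(policy, config = game_config()) {
  n <- config$rounds_total
  own <- character(0); opp <- character(0)
  comp_state <- automaton_init(1L)
  pa <- character(n); ca <- character(n)
  for (t in seq_len(n)) {
    h <- joint_history(own, opp, rounds_total = n)
    a <- policy(h)
    abort_if(!(is.character(a) && length(a) == 1L && a %in% c("C", "D")),
             "policy must return a single 'C' or 'D'")
    endgame <- t > n - config$endgame_defect_rounds
    c_move <- if (endgame) "D" else if (t == 1L) "C" else {
      if (comp_state$punish == 1L) "D" else "C"
    }
    comp_state <- automaton_step(comp_state, a, 2L, "one_coop")
    pa[t] <- a; ca[t] <- c_move
    own <- c(own, a); opp <- c(opp, c_move)
  }
  pay <- payoff(pa, ca, config$matrix)
  data.frame(round = seq_len(n),
             participant_action = pa,
             computer_action = ca,
             participant_payoff = pay$own,
             computer_payoff = pay$opp,
             feedback = feedback_label(pa, config$cond),
             stringsAsFactors = FALSE)
}
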