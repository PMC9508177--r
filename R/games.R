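#' Stage games and abstract actions
#'
#' Each trial of the stochastic game is one play of a two-player matrix game,
#' either a Prisoner's Dilemma (`"PD"`) or a Battle of the Sexes (`"BoS"`).
#' Both players choose among two abstract actions, `"C"` (cooperative) and
#' `"A"` (aggressive), whose game-specific rendering is:
#'
#' * in PD: `C` = Cooperate, `A` = Defect;
#' * in BoS: `C` = play one's own Worst option, `A` = play one's own Best
#'   option (so the players coordinate exactly when they choose different
#'   abstract actions).
#'
#' Payoffs are in Experimental Currency Units (ECU). The participant is the
#' row player; the automaton is the column player.
#'
#' @name stage_games
NULL

#' @rdname stage_games
#' @export
GAMES <- c("PD", "BoS")

#' @rdname stage_games
#' @export
ACTIONS <- c("C", "A")

#' @rdname stage_games
#' @export
AUTOMATON_TYPES <- c("AD", "GT", "TfT")

## participant payoff matrices, rows = participant action, cols = opponent
.PAYOFF <- list(
  PD = matrix(c(48, 12, 50, 25), nrow = 2, byrow = TRUE,
              dimnames = list(ACTIONS, ACTIONS)),
  ## a = A is Best_1: gets 48 when opponent plays Worst_2 (C), 0 on clash;
  ## a = C is Worst_1: gets 25 when opponent plays Best_2 (A), 0 on clash
  BoS = matrix(c(0, 25, 48, 0), nrow = 2, byrow = TRUE,
               dimnames = list(ACTIONS, ACTIONS))
)

## opponent (automaton) payoffs, same orientation
.PAYOFF_OPP <- list(
  PD = matrix(c(48, 50, 12, 25), nrow = 2, byrow = TRUE,
              dimnames = list(ACTIONS, ACTIONS)),
  BoS = matrix(c(0, 48, 25, 0), nrow = 2, byrow = TRUE,
               dimnames = list(ACTIONS, ACTIONS))
)

#' Stage-game definition
#'
#' Returns the payoff tables of one stage game. `stage_payoff()` looks up the
#' participant's (and optionally the opponent's) ECU payoff for an action
#' pair, using the abstract action labels `"C"`/`"A"` for both players.
#'
#' @param game `"PD"` or `"BoS"`.
#' @return For `stage_game()`, a list with elements `name`, `payoff`
#'   (participant ECU, participant action in rows) and `payoff_opponent`.
#' @examples
#' stage_payoff("PD", "C", "C")   # mutual cooperation: 48
#' stage_payoff("BoS", "C", "A")  # coordinate on opponent's Best: 25
#' @export
stage_game <- function(game = c("PD", "BoS")) {
  game <- match.arg(game)
  list(name = game, payoff = .PAYOFF[[game]], payoff_opponent = .PAYOFF_OPP[[game]])
}

#' @rdname stage_game
#' @param action participant action, `"C"` or `"A"`.
#' @param opponent_action automaton action, `"C"` or `"A"`.
#' @param both if `TRUE` return `c(participant, opponent)` payoffs.
#' @export
stage_payoff <- function(game, action, opponent_action, both = FALSE) {
  game <- match.arg(game, GAMES)
  action <- match.arg(action, ACTIONS)
  opponent_action <- match.arg(opponent_action, ACTIONS)
  p <- .PAYOFF[[game]][action, opponent_action]
  if (!both) return(unname(p))
  c(participant = unname(p),
    opponent = unname(.PAYOFF_OPP[[game]][action, opponent_action]))
}

#' Game-specific rendering of an abstract action
#'
#' @param game `"PD"` or `"BoS"`.
#' @param action `"C"` or `"A"`.
#' @param player `1` for the participant (row player), `2` for the automaton.
#' @return A label such as `"Coop"`, `"Def"`, `"Best"`, `"Worst"`.
#' @export
render_action <- function(game, action, player = 1) {
  game <- match.arg(game, GAMES)
  action <- match.arg(action, ACTIONS)
  if (game == "PD") {
    lab <- if (action == "C") "Coop" else "Def"
  } else {
    lab <- if (action == "C") "Worst" else "Best"
  }
  paste0(lab, player)
}

.other_game <- function(game) if (game == "PD") "BoS" else "PD"
.other_action <- function(action) if (action == "C") "A" else "C"
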