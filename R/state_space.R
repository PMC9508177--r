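#' The reduced environment state space
#'
#' The decision-maker's situation is summarized by a state
#' `s = (theta, g, x, y, z)`: opponent type, stage game and the automaton's
#' internal flags. Exploiting the structure of the automata (AD needs no
#' flags; a retaliating GT is indistinguishable from AD) the space reduces to
#' 26 states: a block of 10 with `theta` in {AD, GT} and a block of 16 with
#' `theta = TfT`. No transition crosses the two blocks while the partner
#' stays, so each block is invariant.
#'
#' The canonical ordering is lexicographic in (type block, game, x, y, z)
#' with types ordered AD, GT, TfT; games PD, BoS; `x`, `y` ascending; `z`
#' ordered `b`, `w`. All arrays, logs and exports use this ordering.
#'
#' @return A data frame with one row per state: `index`, `label`, `theta`,
#'   `game`, `x`, `y`, `z`, and `opponent_action` (the automaton's action in
#'   that state).
#' @examples
#' s <- enumerate_states()
#' nrow(s)                      # 26
#' table(s$theta)               # AD 2, GT 8, TfT 16
#' @export
enumerate_states <- function() {
  rows <- list()
  add <- function(theta, game, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      theta = theta, game = game, x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  }
  for (g in GAMES) add("AD", g, NA_integer_, NA_integer_, NA_character_)
  for (g in GAMES) for (x in 0:1) for (z in c("b", "w"))
    add("GT", g, x, NA_integer_, z)
  for (g in GAMES) for (x in 0:1) for (y in 0:1) for (z in c("b", "w"))
    add("TfT", g, x, y, z)
  s <- do.call(rbind, rows)
  s <- s[order(match(s$theta, AUTOMATON_TYPES)), , drop = FALSE]
  s$index <- seq_len(nrow(s))
  s$label <- state_label(s$theta, s$game, s$x, s$y, s$z)
  s$opponent_action <- vapply(seq_len(nrow(s)), function(i) {
    automaton_behavior(s$theta[i],
                       list(x = s$x[i], y = s$y[i], z = s$z[i]), s$game[i])
  }, character(1))
  rownames(s) <- s$label
  s[, c("index", "label", "theta", "game", "x", "y", "z", "opponent_action")]
}

#' Canonical state labels
#'
#' `"AD:PD"`, `"GT:BoS:1w"`, `"TfT:PD:00b"`, ... (flags in the order `x`,
#' `y`, `z`; GT omits the unstored `y`).
#'
#' @param theta,game,x,y,z state components (vectorized).
#' @export
state_label <- function(theta, game, x, y, z) {
  flags <- ifelse(theta == "AD", "",
           ifelse(theta == "GT", paste0(":", x, z), paste0(":", x, y, z)))
  paste0(theta, ":", game, flags)
}

## cached state table and index lookup
.state_env <- new.env(parent = emptyenv())

.states <- function() {
  if (is.null(.state_env$tab)) .state_env$tab <- enumerate_states()
  .state_env$tab
}

.state_index <- function(theta, game, x, y, z) {
  idx <- match(state_label(theta, game, x, y, z), .states()$label)
  if (anyNA(idx)) stop("unknown environment state", call. = FALSE)
  idx
}

#' Parameters of Nature's choices
#'
#' The probabilities governing the stochastic game: `delta`, the probability
#' that the experiment continues; `xi`, the probability of keeping the same
#' opponent (conditional on continuing); `rho`, the probability of keeping
#' the same stage game (conditional on the same opponent). Defaults
#' `delta = 0.9`, `xi = 0.75`, `rho = 0.67`.
#'
#' @param delta,xi,rho probabilities in (0, 1).
#' @return A list of class `nature_params`.
#' @export
nature_params <- function(delta = 0.9, xi = 0.75, rho = 0.67) {
  for (nm in c("delta", "xi", "rho")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop(sprintf("'%s' must be a single probability strictly in (0, 1)", nm),
           call. = FALSE)
  }
  structure(list(delta = delta, xi = xi, rho = rho), class = "nature_params")
}

#' @export
print.nature_params <- function(x, ...) {
  cat(sprintf("<nature_params> delta = %g, xi = %g, rho = %g\n",
              x$delta, x$xi, x$rho))
  invisible(x)
}

#' Deterministic flag successors
#'
#' For every state and participant action, the automaton's flag update is
#' deterministic; only the game switch (and partner switch) is random. This
#' helper returns, for one action, the canonical index of the successor state
#' under "same game" and under "game changed".
#'
#' @param action `"C"` or `"A"`.
#' @return An integer matrix `26 x 2` with columns `same` and `changed`.
#' @keywords internal
.det_successors <- function(action) {
  s <- .states()
  n <- nrow(s)
  out <- matrix(NA_integer_, n, 2, dimnames = list(s$label, c("same", "changed")))
  for (i in seq_len(n)) {
    nxt <- automaton_transition(s$theta[i],
                                list(x = s$x[i], y = s$y[i], z = s$z[i]),
                                s$game[i], action)
    out[i, "same"] <- .state_index(nxt$type, s$game[i],
                                   nxt$flags$x, nxt$flags$y, nxt$flags$z)
    out[i, "changed"] <- .state_index(nxt$type, .other_game(s$game[i]),
                                      nxt$flags$x, nxt$flags$y, nxt$flags$z)
  }
  out
}

#' Action-conditional transition map
#'
#' Builds `T_a(s', s)`, the probability of moving to state `s'` from state
#' `s` when the participant plays `a`, excluding the opponent-change and
#' termination mass: rows sum to `xi`, with mass `xi * rho` on the same-game
#' successor and `xi * (1 - rho)` on the changed-game successor of the
#' deterministic flag update. The matrix is block diagonal over the AD/GT
#' block (states 1-10) and the TfT block (states 11-26). The continuation
#' probability `delta` is applied separately, in the Bellman operator.
#'
#' @param params a [nature_params()] object.
#' @param action `"C"` or `"A"`.
#' @param full if `TRUE`, reinstate the opponent-change mass `1 - xi`,
#'   spread uniformly over the six initial states (three types x two initial
#'   games); rows then sum to 1. Used for the partner-change invariance
#'   check of the solver.
#' @return A `26 x 26` matrix, rows = current state `s` (canonical order),
#'   columns = successor `s'`.
#' @examples
#' Tm <- build_transition_map(nature_params(), "C")
#' all(abs(rowSums(Tm) - 0.75) < 1e-12)
#' @export
build_transition_map <- function(params = nature_params(), action,
                                 full = FALSE) {
  stopifnot(inherits(params, "nature_params"))
  action <- match.arg(action, ACTIONS)
  s <- .states()
  n <- nrow(s)
  det <- .det_successors(action)
  P <- matrix(0, n, n, dimnames = list(s$label, s$label))
  for (i in seq_len(n)) {
    P[i, det[i, "same"]] <- P[i, det[i, "same"]] + params$xi * params$rho
    P[i, det[i, "changed"]] <- P[i, det[i, "changed"]] +
      params$xi * (1 - params$rho)
  }
  if (full) {
    init <- .initial_state_indices()
    P[, init] <- P[, init] + (1 - params$xi) / length(init)
  }
  attr(P, "action") <- action
  attr(P, "params") <- params
  attr(P, "full") <- full
  P
}

## indices of the six fresh-relationship states (type x initial game)
.initial_state_indices <- function() {
  vapply(AUTOMATON_TYPES, function(ty) {
    fl <- automaton_initial_flags(ty)
    vapply(GAMES, function(g) .state_index(ty, g, fl$x, fl$y, fl$z),
           integer(1))
  }, integer(2))  # 2 games x 3 types
}

#' Reduced payoff function
#'
#' `u(s, a)`: the participant's stage payoff in ECU when playing `a` in
#' state `s`, against the automaton's action in that state.
#'
#' @param state a state label (e.g. `"AD:PD"`), canonical index, or a
#'   one-row slice of [enumerate_states()].
#' @param action `"C"` or `"A"`.
#' @examples
#' reduced_payoff("GT:PD:0b", "C")  # mutual cooperation: 48
#' reduced_payoff("AD:PD", "A")     # mutual defection: 25
#' reduced_payoff("AD:BoS", "C")    # coordinate on AD's Best: 25
#' @export
reduced_payoff <- function(state, action) {
  i <- .resolve_state(state)
  s <- .states()
  stage_payoff(s$game[i], match.arg(action, ACTIONS), s$opponent_action[i])
}

.resolve_state <- function(state) {
  s <- .states()
  if (is.character(state)) {
    i <- match(state, s$label)
  } else if (is.numeric(state)) {
    i <- as.integer(state)
    i[i < 1L | i > nrow(s)] <- NA_integer_
  } else if (is.data.frame(state)) {
    i <- match(state_label(state$theta, state$game, state$x, state$y, state$z),
               s$label)
  } else {
    i <- NA_integer_
  }
  if (anyNA(i)) stop("unknown environment state", call. = FALSE)
  i
}

#' Payoff matrix over the full state space
#'
#' @return A `26 x 2` matrix of ECU payoffs, columns `C` and `A`.
#' @export
payoff_matrix <- function() {
  s <- .states()
  out <- sapply(ACTIONS, function(a)
    vapply(seq_len(nrow(s)), function(i)
      stage_payoff(s$game[i], a, s$opponent_action[i]), numeric(1)))
  dimnames(out) <- list(s$label, ACTIONS)
  out
}

#' Export transition maps as a long table
#'
#' One row per `(state, action, successor)` with nonzero probability; a
#' plain-text view for inspection and for brute-force oracles.
#'
#' @inheritParams build_transition_map
#' @export
transition_table <- function(params = nature_params(), full = FALSE) {
  out <- do.call(rbind, lapply(ACTIONS, function(a) {
    P <- build_transition_map(params, a, full = full)
    idx <- which(P > 0, arr.ind = TRUE)
    data.frame(state = rownames(P)[idx[, 1]], action = a,
               successor = colnames(P)[idx[, 2]],
               probability = P[idx], stringsAsFactors = FALSE)
  }))
  out[order(match(out$state, .states()$label), out$action), ]
}
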