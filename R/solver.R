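#' One application of the Bellman operator
#'
#' `B(phi)(s) = max_a [ (1 - delta) u(s, a) + delta * sum_s' T_a(s', s) phi(s') ]`.
#' The `(1 - delta)` normalization puts values on a per-period ECU scale.
#' Because the reduced transition maps carry only the stay-with-partner mass
#' (`rowSums = xi`), the effective modulus of contraction is `delta * xi`.
#'
#' @param phi numeric vector over the 26 canonical states (the candidate
#'   value function).
#' @param params a [nature_params()] object.
#' @param tmaps list of transition matrices per action, as built by
#'   [build_transition_map()]; defaults are rebuilt from `params`.
#' @param U payoff matrix from [payoff_matrix()].
#' @return Numeric vector `B(phi)` over the canonical states.
#' @export
bellman_step <- function(phi, params = nature_params(), tmaps = NULL, U = NULL) {
  if (is.null(tmaps))
    tmaps <- lapply(ACTIONS, function(a) build_transition_map(params, a))
  if (is.null(U)) U <- payoff_matrix()
  stopifnot(length(phi) == nrow(U))
  q <- vapply(seq_along(ACTIONS), function(k) {
    (1 - params$delta) * U[, k] + params$delta * drop(tmaps[[k]] %*% phi)
  }, numeric(length(phi)))
  apply(q, 1, max)
}

#' Solve the dynamic program by value iteration
#'
#' Iterates the Bellman operator to its fixed point `V`, then computes the
#' action values `Q(s, a)`, the per-trial loss `L(s, a) = V(s) - Q(s, a)`,
#' and the greedy optimal policy (argmax of `Q`, ties kept as sets).
#'
#' @param params a [nature_params()] object.
#' @param tol sup-norm stopping threshold on successive iterates
#'   (default `1e-10`).
#' @param model `"reduced"` drops the opponent-change mass from the
#'   transition maps (the default model); `"full"` reinstates it, spread
#'   uniformly over the six fresh-relationship states. The two differ only
#'   by a constant shift of `V`; `Q` differences, losses and the policy are
#'   identical.
#' @param tie_tol numerical tolerance for declaring an argmax tie.
#' @return An object of class `value_solution`: list with `V` (named vector),
#'   `Q`, `L` (`26 x 2` matrices), `policy` (list of optimal action sets per
#'   state), `policy_action` (single action per state, `C` preferred on
#'   ties), `iterations`, `tol`, `params`, `model`.
#' @examples
#' sol <- solve_values()
#' sol$policy_action["AD:PD"]   # "A"
#' sol$policy_action["AD:BoS"]  # "C"
#' @export
solve_values <- function(params = nature_params(), tol = 1e-10,
                         model = c("reduced", "full"), tie_tol = 1e-9) {
  model <- match.arg(model)
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0)
    stop("'tol' must be a single positive number", call. = FALSE)
  full <- model == "full"
  tmaps <- lapply(ACTIONS, function(a)
    build_transition_map(params, a, full = full))
  U <- payoff_matrix()
  s <- .states()

  ## geometric convergence: modulus delta (full) or delta * xi (reduced)
  beta <- params$delta * if (full) 1 else params$xi
  max_iter <- ceiling(log(tol * (1 - beta) / diff(range(U))) / log(beta)) + 10L

  v <- numeric(nrow(s))
  it <- 0L
  repeat {
    v_new <- bellman_step(v, params, tmaps, U)
    it <- it + 1L
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
    if (it > max_iter)
      stop("value iteration failed to converge within the geometric bound",
           call. = FALSE)  # should be impossible
  }

  Q <- vapply(seq_along(ACTIONS), function(k) {
    (1 - params$delta) * U[, k] + params$delta * drop(tmaps[[k]] %*% v)
  }, numeric(length(v)))
  dimnames(Q) <- list(s$label, ACTIONS)
  V <- apply(Q, 1, max)
  L <- V - Q
  policy <- lapply(seq_len(nrow(Q)), function(i)
    ACTIONS[L[i, ] <= tie_tol])
  names(policy) <- s$label
  policy_action <- vapply(policy, `[`, character(1), 1L)  # C ordered first

  structure(
    list(V = V, Q = Q, L = L, policy = policy, policy_action = policy_action,
         iterations = it, tol = tol, params = params, model = model),
    class = "value_solution")
}

#' @export
print.value_solution <- function(x, ...) {
  cat(sprintf(
    "<value_solution> %s model, %d states, %d iterations (tol %.1e)\n",
    x$model, length(x$V), x$iterations, x$tol))
  cat(sprintf("  delta = %g, xi = %g, rho = %g; values on per-period ECU scale\n",
              x$params$delta, x$params$xi, x$params$rho))
  invisible(x)
}

#' Tabular export of a value solution
#'
#' @param x a `value_solution`.
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return A data frame: state label, V, Q and L per action, optimal actions.
#' @export
as.data.frame.value_solution <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    state = names(x$V), V = unname(x$V),
    Q_C = unname(x$Q[, "C"]), Q_A = unname(x$Q[, "A"]),
    L_C = unname(x$L[, "C"]), L_A = unname(x$L[, "A"]),
    optimal = vapply(x$policy, paste, character(1), collapse = "/"),
    stringsAsFactors = FALSE, row.names = row.names)
}

#' Per-trial loss of a choice
#'
#' `L(s, a) = V(s) - Q(s, a)`: the non-negative cost (per-period ECU scale)
#' of choosing `a` in state `s`; zero exactly for optimal actions.
#'
#' @param state state label, canonical index, or data-frame slice.
#' @param action `"C"` or `"A"` (vectorized with `state`).
#' @param solution a [solve_values()] result.
#' @export
score_loss <- function(state, action, solution) {
  stopifnot(inherits(solution, "value_solution"))
  i <- .resolve_state(state)
  k <- match(action, ACTIONS)
  if (anyNA(k)) stop("unknown action", call. = FALSE)
  unname(solution$L[cbind(i, k)])
}

#' Finite-horizon expectimax value (brute-force oracle)
#'
#' Independent check of the value-iteration solution: computes the optimal
#' expected normalized payoff over an explicit game tree of depth `horizon`
#' by stepping the automaton engine one trial at a time (it does not use the
#' transition matrices). The truncation error is at most
#' `(delta * xi)^horizon * max(payoff)` in the reduced model.
#'
#' @param state a state label or index.
#' @param horizon tree depth.
#' @param params a [nature_params()] object.
#' @return The expectimax value of `state`.
#' @export
expectimax_value <- function(state, horizon, params = nature_params()) {
  s <- .states()
  i0 <- .resolve_state(state)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, h) {
    if (h == 0L) return(0)
    key <- paste0(i, ".", h)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    for (a in ACTIONS) {
      u <- stage_payoff(s$game[i], a, s$opponent_action[i])
      nxt <- automaton_transition(s$theta[i],
                                  list(x = s$x[i], y = s$y[i], z = s$z[i]),
                                  s$game[i], a)
      i_same <- .state_index(nxt$type, s$game[i],
                             nxt$flags$x, nxt$flags$y, nxt$flags$z)
      i_chg <- .state_index(nxt$type, .other_game(s$game[i]),
                            nxt$flags$x, nxt$flags$y, nxt$flags$z)
      cont <- params$xi * (params$rho * rec(i_same, h - 1L) +
                           (1 - params$rho) * rec(i_chg, h - 1L))
      val <- (1 - params$delta) * u + params$delta * cont
      if (val > best) best <- val
    }
    memo[[key]] <- best
    best
  }
  rec(i0, as.integer(horizon))
}
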