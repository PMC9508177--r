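#' Trial-sequence configuration
#'
#' Settings for generating experiment-like sequences of Nature's choices.
#' Two modes are supported:
#'
#' * `"constrained"` (default): fixed-length runs with an exact composition
#'   of change types, mirroring the scanner design — 48 trials per run, of
#'   which 24 keep both game and partner, 12 change only the game and 12
#'   change only the partner. Game and partner never change on the same
#'   trial. This composition realizes a partner-stay fraction of 0.75 and a
#'   same-game-given-same-partner fraction of 24/36.
#' * `"iid"`: each trial independently draws a partner change (probability
#'   `1 - xi`) or, staying with the partner, a game change (probability
#'   `1 - rho`), matching the generative assumptions of the model.
#'   Termination is disabled for fixed-length runs.
#'
#' @param mode `"constrained"` or `"iid"`.
#' @param run_length trials per run (default 48).
#' @param composition named counts `c(none, game, partner)` summing to
#'   `run_length` (constrained mode; default `c(24, 12, 12)`).
#' @param n_runs number of runs (default 6).
#' @param players data frame with columns `name`, `type`
#'   (default [default_players()]: six names, two per automaton type).
#' @param xi,rho Nature's probabilities, used by iid mode.
#' @param allow_self_redraw if `TRUE` a partner change may redraw the same
#'   name; default `FALSE` (uniform over the other five names).
#' @param seed optional integer seed.
#' @return A list of class `sequence_config`.
#' @export
sequence_config <- function(mode = c("constrained", "iid"),
                            run_length = 48L,
                            composition = c(none = 24L, game = 12L, partner = 12L),
                            n_runs = 6L,
                            players = default_players(),
                            xi = 0.75, rho = 0.67,
                            allow_self_redraw = FALSE,
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(players), all(c("name", "type") %in% names(players)),
            all(players$type %in% AUTOMATON_TYPES), !anyDuplicated(players$name),
            run_length >= 1L, n_runs >= 1L)
  composition <- as.integer(composition)
  names(composition) <- c("none", "game", "partner")
  if (mode == "constrained" && sum(composition) != run_length)
    stop("composition must sum to run_length", call. = FALSE)
  structure(list(mode = mode, run_length = as.integer(run_length),
                 composition = composition, n_runs = as.integer(n_runs),
                 players = players, xi = xi, rho = rho,
                 allow_self_redraw = isTRUE(allow_self_redraw),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sequence_config")
}

#' Generate a sequence of Nature's choices
#'
#' Produces the per-trial schedule of opponent, stage game and change type.
#' Each run starts from a uniformly drawn (pre-run) opponent and game to
#' which the first trial's change type is applied; automata start each run
#' at their initial condition. On a partner change the game is kept
#' (constrained mode; the two changes never coincide) and the new opponent
#' is drawn uniformly over the other names.
#'
#' @param config a [sequence_config()].
#' @return A data frame with columns `run`, `trial`, `change_type`
#'   (`"none"`, `"game"` or `"partner"`), `opponent`, `theta`, `game`.
#' @examples
#' sq <- generate_sequence(sequence_config(seed = 1))
#' table(sq$change_type)
#' @export
generate_sequence <- function(config = sequence_config()) {
  stopifnot(inherits(config, "sequence_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nm <- config$players$name
  runs <- lapply(seq_len(config$n_runs), function(r) {
    if (config$mode == "constrained") {
      labels <- sample(rep(names(config$composition), config$composition))
    } else {
      u <- stats::runif(config$run_length)
      labels <- ifelse(u < 1 - config$xi, "partner",
                ifelse(u < 1 - config$xi + config$xi * (1 - config$rho),
                       "game", "none"))
    }
    opp <- character(config$run_length)
    game <- character(config$run_length)
    cur_opp <- sample(nm, 1L)
    cur_game <- sample(GAMES, 1L)
    for (t in seq_len(config$run_length)) {
      if (labels[t] == "partner") {
        pool <- if (config$allow_self_redraw) nm else setdiff(nm, cur_opp)
        cur_opp <- sample(pool, 1L)
        if (config$mode == "iid")  # fresh relationship: initial game redrawn
          cur_game <- sample(GAMES, 1L)
      } else if (labels[t] == "game") {
        cur_game <- .other_game(cur_game)
      }
      opp[t] <- cur_opp
      game[t] <- cur_game
    }
    data.frame(run = r, trial = seq_len(config$run_length),
               change_type = labels, opponent = opp,
               theta = config$players$type[match(opp, nm)],
               game = game, stringsAsFactors = FALSE)
  })
  do.call(rbind, runs)
}

## precomputed integer tables used by the trial-stepping loops
.sim_tables <- function() {
  if (is.null(.state_env$sim)) {
    s <- .states()
    init <- .initial_state_indices()          # 2 games x 3 types
    .state_env$sim <- list(
      states = s,
      det = lapply(stats::setNames(ACTIONS, ACTIONS), .det_successors),
      init = init,
      opp_action = s$opponent_action,
      U = payoff_matrix()
    )
  }
  .state_env$sim
}

#' Play a session against the automata
#'
#' Steps an agent through a generated sequence, updating the automaton via
#' its transition rule and recording one row per trial.
#'
#' @param sequence a data frame from [generate_sequence()].
#' @param agent either a named character vector mapping state labels to
#'   actions (e.g. `solve_values()$policy_action`), or a function taking the
#'   one-row state slice of [enumerate_states()] and returning `"C"` or
#'   `"A"`.
#' @param subject subject identifier recorded in the log.
#' @param seed optional seed (only relevant for stochastic agents).
#' @return A trial-log data frame: `subject`, `run`, `trial`, `opponent`,
#'   `theta`, `game`, `change_type`, `state`, `action`, `opponent_action`,
#'   `payoff`, `rt` (NA; filled by generators that model response times),
#'   `loss` (NA; filled by [score_dataset()]).
#' @examples
#' sol <- solve_values()
#' log <- play_session(generate_sequence(sequence_config(seed = 2)),
#'                     sol$policy_action)
#' sum(score_dataset(log, sol)$trials$loss)  # 0 under the optimal policy
#' @export
play_session <- function(sequence, agent, subject = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- .sim_tables()
  s <- tb$states
  n <- nrow(sequence)
  agent_fun <- if (is.function(agent)) {
    function(i) agent(s[i, ])
  } else {
    pol <- agent
    function(i) pol[[s$label[i]]]
  }

  state <- integer(n); action <- character(n)
  opp_act <- character(n); payoff <- numeric(n)
  cur <- NA_integer_
  for (t in seq_len(n)) {
    first <- t == 1L || sequence$run[t] != sequence$run[t - 1L]
    if (first || sequence$change_type[t] == "partner") {
      cur <- tb$init[match(sequence$game[t], GAMES),
                     match(sequence$theta[t], AUTOMATON_TYPES)]
    } else {
      same <- sequence$change_type[t] == "none"
      cur <- tb$det[[action[t - 1L]]][state[t - 1L],
                                      if (same) "same" else "changed"]
    }
    a <- agent_fun(cur)
    if (!is.character(a) || length(a) != 1L || !a %in% ACTIONS)
      stop(sprintf("agent returned an invalid action at trial %d of run %d",
                   sequence$trial[t], sequence$run[t]), call. = FALSE)
    state[t] <- cur
    action[t] <- a
    opp_act[t] <- tb$opp_action[cur]
    payoff[t] <- tb$U[cur, a]
  }

  data.frame(subject = subject, run = sequence$run, trial = sequence$trial,
             opponent = sequence$opponent, theta = sequence$theta,
             game = sequence$game, change_type = sequence$change_type,
             state = s$label[state], action = action,
             opponent_action = opp_act, payoff = payoff,
             rt = NA_real_, loss = NA_real_, stringsAsFactors = FALSE)
}

#' Optimal-policy agent
#'
#' @param solution a [solve_values()] result.
#' @return A named action vector usable as the `agent` of [play_session()].
#' @export
optimal_agent <- function(solution) {
  stopifnot(inherits(solution, "value_solution"))
  solution$policy_action
}

#' Validate a trial log against the model
#'
#' Replays every `(subject, run)` through the automaton engine from the last
#' partner change and checks that the recorded states, opponent actions and
#' payoffs are consistent. Fails with the coordinates of the first mismatch.
#'
#' @param log a trial-log data frame.
#' @return Invisibly `TRUE`.
#' @export
validate_trial_log <- function(log) {
  req <- c("subject", "run", "trial", "theta", "game", "change_type",
           "state", "action", "opponent_action", "payoff")
  miss <- setdiff(req, names(log))
  if (length(miss))
    stop("trial log is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tb <- .sim_tables()
  s <- tb$states
  idx <- match(log$state, s$label)
  if (anyNA(idx))
    stop("unknown state label at row ", which(is.na(idx))[1], call. = FALSE)
  fail <- function(what, i)
    stop(sprintf("inconsistent trial log (%s) at subject %s, run %d, trial %d",
                 what, log$subject[i], log$run[i], log$trial[i]),
         call. = FALSE)
  bad <- which(log$opponent_action != tb$opp_action[idx])
  if (length(bad)) fail("opponent action mismatch", bad[1])
  bad <- which(log$payoff != tb$U[cbind(idx, match(log$action, ACTIONS))])
  if (length(bad)) fail("payoff mismatch", bad[1])
  ## a retaliating GT occupies the AD-equivalent block while the opponent
  ## is still the GT player, so state theta "AD" is consistent with theta "GT"
  theta_ok <- s$theta[idx] == log$theta |
    (s$theta[idx] == "AD" & log$theta == "GT")
  bad <- which(!theta_ok | s$game[idx] != log$game)
  if (length(bad)) fail("state/context mismatch", bad[1])
  ## replay transitions within each subject x run
  ord <- order(log$subject, log$run, log$trial)
  lo <- log[ord, ]; li <- idx[ord]
  new_seg <- c(TRUE, lo$subject[-1] != lo$subject[-nrow(lo)] |
                 lo$run[-1] != lo$run[-nrow(lo)])
  for (t in seq_len(nrow(lo))) {
    if (new_seg[t] || lo$change_type[t] == "partner") {
      expected <- tb$init[match(lo$game[t], GAMES),
                          match(lo$theta[t], AUTOMATON_TYPES)]
    } else {
      same <- lo$change_type[t] == "none"
      expected <- tb$det[[lo$action[t - 1L]]][li[t - 1L],
                                              if (same) "same" else "changed"]
    }
    if (li[t] != expected) fail("state replay mismatch", ord[t])
  }
  invisible(TRUE)
}

#' Write / read trial logs as delimited text
#'
#' Tab-separated logs with a commented header carrying provenance
#' (`# key: value` lines: seed, config echo, column dictionary). The
#' round trip `read_trial_log(write_trial_log(x))` is lossless.
#'
#' @param log a trial-log data frame.
#' @param path file path.
#' @param header named list of values to echo in comment lines.
#' @export
write_trial_log <- function(log, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(header),
                     vapply(header, function(v) paste(format(v), collapse = " "),
                            character(1))), con)
  writeLines(paste0("# columns: ", paste(names(log), collapse = " ")), con)
  utils::write.table(log, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
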