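#' Synthetic-cohort configuration
#'
#' Settings for generating cohorts of artificial subjects whose choices and
#' response times carry the statistical structure the behavioral analysis
#' assumes: per-trial error rates that rise with environment complexity,
#' more steeply for the low-ability group, and RTs that increase with
#' complexity.
#'
#' The default choice model is a state-blind error rate
#' `eps_g(c) = plogis(alpha_g + beta_g * c)` where `c` is the complexity
#' index of the current environment: with probability `1 - eps` the agent
#' plays an optimal action, otherwise the other one. Error rates are capped
#' at 0.5. The defaults (`alpha` = -1.6/-1.9/-2.1, `beta` = 0.25/0.15/0.12
#' for low/medium/high) give roughly 84% optimal choices overall, with the
#' low-ability group most affected by complexity. An alternative
#' softmax-on-Q agent is available via `choice_model = "softmax"`.
#'
#' RTs are `rt_intercept_g + rt_slope * cnorm + N(0, rt_sd)` ms, where
#' `cnorm` in \[0, 1\] is the complexity index rescaled over its range, so
#' `rt_slope` is the expected RT increase (default 150 ms) across the whole
#' complexity range; values are truncated to the (0, 3000\] ms response
#' window.
#'
#' @param n_subjects total subjects (default 42).
#' @param group_sizes named integer vector `c(low, medium, high)` summing to
#'   `n_subjects` (default 16/14/12).
#' @param ability_mean,ability_sd per-group parameters of the synthetic
#'   ability score (a Raven-like integer in 0..36).
#' @param alpha,beta per-group intercept and complexity slope of the
#'   error-rate link (logit scale).
#' @param rt_intercept per-group RT intercept (ms).
#' @param rt_slope common RT increase over the complexity range (ms).
#' @param rt_sd RT noise SD (ms).
#' @param choice_model `"epsilon"` (default) or `"softmax"`.
#' @param softmax_temp per-group softmax temperature (per-period ECU), used
#'   only by the softmax agent.
#' @param sequence a [sequence_config()] for the per-subject sessions
#'   (default: 6 constrained runs of 48 trials).
#' @param seed root seed; per-subject substreams are derived from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 42L,
                          group_sizes = c(low = 16L, medium = 14L, high = 12L),
                          ability_mean = c(low = 14, medium = 22, high = 28),
                          ability_sd = c(low = 3, medium = 2, high = 2),
                          alpha = c(low = -1.6, medium = -1.9, high = -2.1),
                          beta = c(low = 0.25, medium = 0.15, high = 0.12),
                          rt_intercept = c(low = 800, medium = 800, high = 800),
                          rt_slope = 150,
                          rt_sd = 250,
                          choice_model = c("epsilon", "softmax"),
                          softmax_temp = c(low = 0.6, medium = 0.45, high = 0.35),
                          sequence = sequence_config(),
                          seed = NULL) {
  choice_model <- match.arg(choice_model)
  grp <- c("low", "medium", "high")
  for (nm in c("group_sizes", "ability_mean", "ability_sd", "alpha", "beta",
               "rt_intercept", "softmax_temp")) {
    v <- get(nm)
    if (length(v) != 3L)
      stop(sprintf("'%s' must have one value per group", nm), call. = FALSE)
    if (is.null(names(v))) names(v) <- grp
  }
  if (sum(group_sizes) != n_subjects)
    stop("group sizes must sum to n_subjects", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 group_sizes = group_sizes, ability_mean = ability_mean,
                 ability_sd = ability_sd, alpha = alpha, beta = beta,
                 rt_intercept = rt_intercept, rt_slope = rt_slope,
                 rt_sd = rt_sd, choice_model = choice_model,
                 softmax_temp = softmax_temp, sequence = sequence,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

## complexity of the faced condition for every (state, opponent type) pair:
## a 26 x 3 matrix (columns AD, GT, TfT); a retaliating GT occupies AD-block
## states but the condition complexity is still that of (GT, game)
.pair_complexity <- function(table) {
  s <- .states()
  out <- sapply(AUTOMATON_TYPES, function(ty)
    complexity(rep(ty, nrow(s)), s$game, table))
  rownames(out) <- s$label
  out
}

## probability of playing A for each (state, opponent type), for one group
.choice_prob_A <- function(config, group, solution, cxp) {
  opt <- solution$policy_action
  if (config$choice_model == "epsilon") {
    eps <- pmin(stats::plogis(config$alpha[[group]] +
                                config$beta[[group]] * cxp), 0.5)
    pA <- eps
    pA[opt == "A", ] <- 1 - eps[opt == "A", ]
    pA
  } else {
    tmp <- config$softmax_temp[[group]]
    pa <- 1 / (1 + exp((solution$Q[, "C"] - solution$Q[, "A"]) / tmp))
    matrix(pa, nrow = length(pa), ncol = length(AUTOMATON_TYPES),
           dimnames = list(names(pa), AUTOMATON_TYPES))
  }
}

## fast trial-stepping loop: integer states and actions (1 = C, 2 = A);
## pA is the 26 x 3 (state x opponent type) choice-probability matrix
.play_noisy <- function(seqdf, pA, tb) {
  n <- nrow(seqdf)
  run <- seqdf$run
  chg <- match(seqdf$change_type, c("none", "game", "partner"))
  gi <- match(seqdf$game, GAMES)
  ti <- match(seqdf$theta, AUTOMATON_TYPES)
  detC <- tb$det[["C"]]; detA <- tb$det[["A"]]
  init <- tb$init
  u <- stats::runif(n)
  state <- integer(n); action <- integer(n)
  cur <- 0L
  for (t in seq_len(n)) {
    if (t == 1L || run[t] != run[t - 1L] || chg[t] == 3L) {
      cur <- init[gi[t], ti[t]]
    } else if (action[t - 1L] == 1L) {
      cur <- detC[cur, chg[t]]   # col 1 = same game, col 2 = changed
    } else {
      cur <- detA[cur, chg[t]]
    }
    state[t] <- cur
    action[t] <- if (u[t] < pA[cur, ti[t]]) 2L else 1L
  }
  list(state = state, action = action)
}

#' Generate a synthetic cohort
#'
#' Simulates one session set (default 6 runs x 48 trials) per subject, with
#' choices from the noisy agent and RTs from the linear RT model.
#'
#' @param config a [cohort_config()].
#' @param solution a [solve_values()] result (defaults computed at
#'   `config`-independent default parameters).
#' @param table a [build_order()] complexity table.
#' @return A list of class `cohort`: `trials` (trial-log data frame with
#'   `group` and `rt` filled and `loss` `NA`), `subjects` (data frame `subject`,
#'   `group`, `ability`), and the `config`.
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_config(seed = 1))
#' nrow(co$trials)  # 42 * 6 * 48
#' }
#' @export
generate_cohort <- function(config = cohort_config(),
                            solution = solve_values(),
                            table = build_order()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(solution, "value_solution"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tb <- .sim_tables()
  cxp <- .pair_complexity(table)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- config$n_subjects
  sub_seeds <- sample.int(.Machine$integer.max, n)
  ability <- pmin(pmax(round(stats::rnorm(
    n, config$ability_mean[groups], config$ability_sd[groups])), 0), 36)
  ids <- sprintf("S%02d", seq_len(n))
  subjects <- data.frame(subject = ids, group = groups, ability = ability,
                         stringsAsFactors = FALSE)

  seq_cfg <- config$sequence
  seq_cfg$seed <- NULL  # substream seeds set explicitly per subject
  pA_by_group <- lapply(stats::setNames(nm = unique(groups)), function(g)
    .choice_prob_A(config, g, solution, cxp))
  cx_range <- range(cxp)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    sq <- generate_sequence(seq_cfg)
    played <- .play_noisy(sq, pA_by_group[[groups[i]]], tb)
    cnorm <- (cxp[cbind(played$state, match(sq$theta, AUTOMATON_TYPES))] -
                cx_range[1]) / diff(cx_range)
    rt <- config$rt_intercept[[groups[i]]] +
      config$rt_slope * cnorm +
      stats::rnorm(nrow(sq), 0, config$rt_sd)
    rt <- pmin(pmax(rt, 1), 3000)
    out[[i]] <- data.frame(
      subject = ids[i], group = groups[i],
      run = sq$run, trial = sq$trial, opponent = sq$opponent,
      theta = sq$theta, game = sq$game, change_type = sq$change_type,
      state = tb$states$label[played$state],
      action = ACTIONS[played$action],
      opponent_action = tb$opp_action[played$state],
      payoff = tb$U[cbind(played$state, played$action)],
      rt = rt, loss = NA_real_, stringsAsFactors = FALSE)
  }
  structure(list(trials = do.call(rbind, out), subjects = subjects,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d trials\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", "),
              nrow(x$trials)))
  invisible(x)
}

#' Analytic expected per-trial loss by group and complexity level
#'
#' The oracle for the cohort generator: for each ability group and
#' complexity level, the expected per-trial loss implied by the error model
#' and the state distribution induced by near-optimal play, computed from
#' the Markov chain over the 26 states (no simulation).
#'
#' @param config a [cohort_config()].
#' @param solution a [solve_values()] result.
#' @param table a [build_order()] complexity table.
#' @param dist `"run_average"` (default): the state distribution averaged
#'   over a finite run started from a uniformly drawn fresh relationship,
#'   matching the constrained-run design; `"stationary"`: the stationary
#'   distribution of the chain.
#' @return A data frame `group`, `complexity`, `expected_loss`.
#' @export
expected_loss_curve <- function(config = cohort_config(),
                                solution = solve_values(),
                                table = build_order(),
                                dist = c("run_average", "stationary")) {
  dist <- match.arg(dist)
  tb <- .sim_tables()
  cxp <- .pair_complexity(table)
  comp <- config$sequence$composition
  if (config$sequence$mode == "constrained") {
    xi <- unname((comp["none"] + comp["game"]) / sum(comp))
    rho <- unname(comp["none"] / (comp["none"] + comp["game"]))
  } else {
    xi <- config$sequence$xi; rho <- config$sequence$rho
  }

  ## chain over (state, opponent type): AD-block states can be faced against
  ## a genuine AD or a retaliating GT, so those two contexts are tracked
  ## separately (28 nodes in total)
  node_state <- c(1L, 2L, 1L, 2L, 3:26)
  node_type <- c("AD", "AD", "GT", "GT", rep("GT", 8), rep("TfT", 16))
  nn <- length(node_state)
  node_id <- matrix(NA_integer_, 26, 3,
                    dimnames = list(tb$states$label, AUTOMATON_TYPES))
  for (k in seq_len(nn)) node_id[node_state[k], node_type[k]] <- k

  init <- tb$init  # 2 games x 3 types
  init_nodes <- sapply(AUTOMATON_TYPES, function(ty)
    node_id[init[, ty], ty])  # 2 games x 3 types
  nu0 <- numeric(nn)
  nu0[init_nodes] <- 1 / 6
  node_level <- cxp[cbind(node_state, match(node_type, AUTOMATON_TYPES))]

  out <- list()
  for (g in names(config$group_sizes)) {
    pA <- .choice_prob_A(config, g, solution, cxp)
    pa_node <- pA[cbind(node_state, match(node_type, AUTOMATON_TYPES))]
    M <- matrix(0, nn, nn)
    for (k in seq_len(nn)) {
      s <- node_state[k]; ty <- node_type[k]
      for (a in 1:2) {  # 1 = C, 2 = A
        pa <- if (a == 2L) pa_node[k] else 1 - pa_node[k]
        det <- tb$det[[ACTIONS[a]]]
        for (gc in 1:2) {  # 1 = same game, 2 = changed
          j <- node_id[det[s, gc], ty]
          M[k, j] <- M[k, j] + pa * xi * (if (gc == 1L) rho else 1 - rho)
        }
      }
      ## partner change keeps the game, uniform over the three types
      gsame <- match(tb$states$game[s], GAMES)
      tgt <- init_nodes[gsame, ]
      M[k, tgt] <- M[k, tgt] + (1 - xi) / 3
    }
    if (dist == "run_average") {
      Tlen <- config$sequence$run_length
      pi_t <- nu0
      acc <- numeric(nn)
      for (t in seq_len(Tlen)) {
        acc <- acc + pi_t
        pi_t <- drop(pi_t %*% M)
      }
      pi_bar <- acc / Tlen
    } else {
      pi_bar <- nu0
      for (t in 1:2000) pi_bar <- drop(pi_bar %*% M)
    }
    ## expected loss of the realized (possibly suboptimal) choice per node
    eLs <- pa_node * solution$L[node_state, "A"] +
      (1 - pa_node) * solution$L[node_state, "C"]
    for (cl in sort(unique(as.vector(cxp)))) {
      w <- pi_bar * (node_level == cl)
      out[[length(out) + 1L]] <- data.frame(
        group = g, complexity = cl,
        expected_loss = sum(w * eLs) / sum(w), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
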