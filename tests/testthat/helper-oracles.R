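# Independent oracles and reference values used across the test files.

# --- published transition-matrix example: participant action C, game BoS ---
# Rows are the current state, columns the successor flag pattern (the actual
# successor splits that pattern over g' = same / changed game).

printed_ad_matrix <- function() {
  m <- matrix(1, 1, 1, dimnames = list("AB", "A"))
  m
}

printed_gt_matrix <- function() {
  cols <- c("A", "G0b", "G0w", "G1b", "G1w")
  rows <- c("AB", "GB0b", "GB0w", "GB1b", "GB1w")
  m <- matrix(c(
    1, 0, 0, 0, 0,
    0, 0, 0, 0, 1,
    0, 1, 0, 0, 0,
    0, 0, 0, 0, 1,
    1, 0, 0, 0, 0), nrow = 5, byrow = TRUE, dimnames = list(rows, cols))
  m
}

printed_tft_matrix <- function() {
  cols <- c("T00b", "T00w", "T01b", "T01w", "T10b", "T10w", "T11b", "T11w")
  rows <- c("TB00b", "TB00w", "TB01b", "TB01w",
            "TB10b", "TB10w", "TB11b", "TB11w")
  m <- matrix(c(
    0, 0, 0, 0, 0, 1, 0, 0,
    1, 0, 0, 0, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0,
    0, 0, 1, 0, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0), nrow = 8, byrow = TRUE,
    dimnames = list(rows, cols))
  m
}

# canonical state label of a row label ("GB0b" -> "GT:BoS:0b"), and the pair
# of successor labels for a column pattern ("G1w" -> c("GT:PD:1w","GT:BoS:1w"))
row_label_to_state <- function(lab) {
  if (lab == "AB") return("AD:BoS")
  theta <- c(A = "AD", G = "GT", T = "TfT")[substr(lab, 1, 1)]
  flags <- substring(lab, 3)
  if (theta == "GT") sprintf("GT:BoS:%s", flags) else
    sprintf("TfT:BoS:%s", flags)
}

col_pattern_to_states <- function(lab) {
  theta <- c(A = "AD", G = "GT", T = "TfT")[substr(lab, 1, 1)]
  flags <- substring(lab, 2)
  if (theta == "AD") return(c("AD:PD", "AD:BoS"))
  sprintf("%s:%s:%s", theta, c("PD", "BoS"), flags)
}

# --- published optimal policy at delta = .9, xi = .75, rho = .67 ----------
# AD: A in PD, C in BoS. GT out of retaliation: C in PD; in BoS coordinate
# with the alternating automaton (C when it is about to play Best, A when
# Worst). TfT: C in every PD state; out of retaliation coordinate in BoS;
# while it retaliates in BoS, play C (coordinate on its Best).
printed_policy <- function() {
  s <- enumerate_states()
  pol <- character(nrow(s))
  names(pol) <- s$label
  for (i in seq_len(nrow(s))) {
    pol[i] <- if (s$theta[i] == "AD") {
      if (s$game[i] == "PD") "A" else "C"
    } else if (s$game[i] == "PD") {
      "C"
    } else if (s$theta[i] == "TfT" && s$y[i] == 1L) {
      "C"
    } else {
      if (s$z[i] == "b") "C" else "A"
    }
  }
  pol
}

# --- brute-force closure oracle for the complexity order ------------------
# Explicit edge list + Floyd-Warshall reachability on the 6 vertices,
# written independently of build_order().
closure_oracle <- function() {
  v <- c("(AD,PD)", "(AD,BoS)", "(GT,PD)", "(GT,BoS)", "(TfT,PD)", "(TfT,BoS)")
  th <- c(1, 1, 2, 2, 3, 3)   # AD < GT < TfT
  gm <- c(1, 2, 1, 2, 1, 2)   # PD < BoS
  n <- 6L
  R <- matrix(FALSE, n, n, dimnames = list(v, v))
  for (i in 1:n) for (j in 1:n)
    if (th[i] >= th[j] && gm[i] >= gm[j]) R[i, j] <- TRUE
  R[1, 2] <- TRUE; R[2, 1] <- TRUE          # the AD-pair equivalence
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (R[i, k] && R[k, j]) R[i, j] <- TRUE
  strict <- R & !t(R)
  list(vertices = v, geq = R, strict = strict,
       scores = setNames(as.integer(rowSums(strict) - colSums(strict)), v))
}

# small cohort for quick module tests: 9 subjects, 2 runs each
small_cohort_config <- function(seed = NULL, ...) {
  cohort_config(n_subjects = 9L,
                group_sizes = c(low = 3L, medium = 3L, high = 3L),
                sequence = sequence_config(n_runs = 2L),
                seed = seed, ...)
}

# shared solution / complexity table (computed once per test run)
shared_solution <- local({
  sol <- NULL
  function() {
    if (is.null(sol)) sol <<- solve_values()
    sol
  }
})

shared_order <- local({
  ct <- NULL
  function() {
    if (is.null(ct)) ct <<- build_order()
    ct
  }
})
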