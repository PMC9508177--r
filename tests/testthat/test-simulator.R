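test_that("constrained runs have the exact design composition", {
  sq <- generate_sequence(sequence_config(seed = 11))
  expect_identical(nrow(sq), 6L * 48L)
  for (r in unique(sq$run)) {
    tab <- table(sq$change_type[sq$run == r])
    expect_identical(as.vector(tab[c("none", "game", "partner")]),
                     as.integer(c(24, 12, 12)))
  }
  # a game change and a partner change never coincide; the per-trial change
  # label is single-valued by construction, so check the realized paths:
  # on partner-change trials the game is unchanged, and vice versa
  for (r in unique(sq$run)) {
    d <- sq[sq$run == r, ]
    for (t in 2:nrow(d)) {
      if (d$change_type[t] == "partner") {
        expect_identical(d$game[t], d$game[t - 1])
        expect_false(d$opponent[t] == d$opponent[t - 1])
      } else if (d$change_type[t] == "game") {
        expect_identical(d$opponent[t], d$opponent[t - 1])
        expect_false(d$game[t] == d$game[t - 1])
      } else {
        expect_identical(d$opponent[t], d$opponent[t - 1])
        expect_identical(d$game[t], d$game[t - 1])
      }
    }
  }
  # implied design frequencies: partner stays 36/48, same game given same
  # partner 24/36
  expect_equal(mean(sq$change_type != "partner"), 0.75)
  expect_equal(sum(sq$change_type == "none") /
                 sum(sq$change_type != "partner"), 24 / 36)
})

test_that("sequences are reproducible and impossible compositions rejected", {
  s1 <- generate_sequence(sequence_config(seed = 5))
  s2 <- generate_sequence(sequence_config(seed = 5))
  expect_identical(s1, s2)
  expect_error(sequence_config(composition = c(10, 10, 10)), "sum")
})

test_that("iid-mode change frequencies match Nature's probabilities", {
  cfg <- sequence_config(mode = "iid", run_length = 10000L, n_runs = 1L,
                         composition = c(none = 10000L, game = 0L, partner = 0L),
                         seed = 3)
  sq <- generate_sequence(cfg)
  p_partner <- mean(sq$change_type == "partner")
  p_game <- mean(sq$change_type == "game")
  expect_lt(abs(p_partner - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(p_game - 0.75 * 0.33), 3 * sqrt(0.2475 * 0.7525 / 10000))
  # xi = 1: the opponent never changes
  cfg1 <- sequence_config(mode = "iid", run_length = 2000L, n_runs = 1L,
                          composition = c(none = 2000L, game = 0L, partner = 0L),
                          xi = 1 - 1e-12, seed = 4)
  sq1 <- generate_sequence(cfg1)
  expect_identical(length(unique(sq1$opponent)), 1L)
})

test_that("the optimal agent sustains cooperation with GT in PD", {
  sol <- shared_solution()
  seqdf <- data.frame(run = 1L, trial = 1:20, change_type = "none",
                      opponent = "Greta", theta = "GT", game = "PD",
                      stringsAsFactors = FALSE)
  log <- play_session(seqdf, optimal_agent(sol))
  expect_true(all(log$payoff == 48))
  expect_true(all(log$opponent_action == "C"))
})

test_that("an always-aggressive agent is absorbed by GT after one PD trial", {
  seqdf <- data.frame(run = 1L, trial = 1:10, change_type = "none",
                      opponent = "Greta", theta = "GT", game = "PD",
                      stringsAsFactors = FALSE)
  log <- play_session(seqdf, function(s) "A")
  expect_identical(log$state[1], "GT:PD:0b")
  expect_true(all(log$state[-1] == "AD:PD"))
  expect_identical(log$payoff, c(50, rep(25, 9)))
})

test_that("a full session under the optimal policy accrues zero loss", {
  sol <- shared_solution()
  sq <- generate_sequence(sequence_config(seed = 21))
  log <- play_session(sq, optimal_agent(sol))
  scored <- score_dataset(log, sol, shared_order())
  expect_identical(sum(scored$trials$loss), 0)
  expect_equal(scored$pct_optimal, 100)
})

test_that("agents emitting invalid actions are rejected with the trial index", {
  sq <- generate_sequence(sequence_config(seed = 22, n_runs = 1L))
  expect_error(play_session(sq, function(s) "defect"), "trial 1")
  seqdf <- data.frame(run = 1L, trial = 1:5, change_type = "none",
                      opponent = "Anna", theta = "AD", game = "PD",
                      stringsAsFactors = FALSE)
  n_seen <- 0L
  bad_late <- function(s) { n_seen <<- n_seen + 1L; if (n_seen > 3L) "Z" else "C" }
  expect_error(play_session(seqdf, bad_late), "trial 4")
})

test_that("trial logs round-trip through text files byte-stably", {
  sol <- shared_solution()
  sq <- generate_sequence(sequence_config(seed = 23, n_runs = 1L))
  log <- play_session(sq, optimal_agent(sol))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_trial_log(log, f1, header = list(seed = 23))
  write_trial_log(log, f2, header = list(seed = 23))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_trial_log(f1)
  expect_equal(back$state, log$state)
  expect_equal(back$payoff, log$payoff)
  expect_identical(nrow(back), nrow(log))
  # a re-written read-back file is byte-identical too
  f3 <- tempfile(fileext = ".tsv")
  back$loss <- NA_real_; back$rt <- NA_real_
  write_trial_log(back, f3, header = list(seed = 23))
  expect_identical(readLines(f1), readLines(f3))
  unlink(c(f1, f2, f3))
})

test_that("the validator replays logs and pinpoints corrupted trials", {
  sol <- shared_solution()
  sq <- generate_sequence(sequence_config(seed = 24, n_runs = 1L))
  log <- play_session(sq, optimal_agent(sol), subject = "S9")
  expect_true(validate_trial_log(log))
  bad <- log
  bad$opponent_action[17] <- setdiff(ACTIONS, bad$opponent_action[17])
  expect_error(validate_trial_log(bad), "S9, run 1, trial 17")
  bad <- log
  bad$payoff[5] <- bad$payoff[5] + 1
  expect_error(validate_trial_log(bad), "payoff")
  bad <- log[, setdiff(names(log), "state")]
  expect_error(validate_trial_log(bad), "missing columns")
})
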