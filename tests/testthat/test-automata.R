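test_that("rules of behavior follow the three strategy definitions", {
  ad <- automaton_initial_flags("AD")
  expect_identical(automaton_behavior("AD", ad, "PD"), "A")
  expect_identical(automaton_behavior("AD", ad, "BoS"), "A")

  # GT out of retaliation: cooperate in PD, play the stored BoS option
  expect_identical(automaton_behavior("GT", list(x = 0L, y = NA, z = "b"), "PD"), "C")
  expect_identical(automaton_behavior("GT", list(x = 1L, y = NA, z = "b"), "BoS"), "A")
  expect_identical(automaton_behavior("GT", list(x = 0L, y = NA, z = "w"), "BoS"), "C")

  # TfT retaliating plays A regardless of game and stored option
  expect_identical(automaton_behavior("TfT", list(x = 0L, y = 1L, z = "b"), "BoS"), "A")
  expect_identical(automaton_behavior("TfT", list(x = 0L, y = 1L, z = "w"), "PD"), "A")
  expect_identical(automaton_behavior("TfT", list(x = 0L, y = 0L, z = "w"), "BoS"), "C")
  expect_identical(automaton_behavior("TfT", list(x = 1L, y = 0L, z = "w"), "PD"), "C")
})

test_that("initial conditions are AD sentinel, GT x=0 z=b, TfT x=0 y=0 z=w", {
  expect_true(is.na(automaton_initial_flags("AD")$x))
  gt <- automaton_initial_flags("GT", "BoS")
  expect_identical(gt[c("x", "z")], list(x = 0L, z = "b"))
  tft <- automaton_initial_flags("TfT", "PD")
  expect_identical(tft, list(x = 0L, y = 0L, z = "w"))
})

test_that("invalid flag combinations are rejected with the flag named", {
  expect_error(automaton_behavior("GT", list(x = NA, y = NA, z = "b"), "PD"), "'x'")
  expect_error(automaton_behavior("GT", list(x = 0L, y = 1L, z = "b"), "PD"), "'y'")
  expect_error(automaton_behavior("AD", list(x = 0L, y = NA, z = NA), "PD"), "'x'")
  expect_error(automaton_transition("TfT", list(x = 0L, y = 0L, z = "q"),
                                    "BoS", "C"), "'z'")
})

test_that("single transitions reproduce worked examples", {
  # GT in BoS, no coordination yet, about to play Worst; participant plays C:
  # no coordination, alternate
  nxt <- automaton_transition("GT", list(x = 0L, y = NA, z = "w"), "BoS", "C")
  expect_identical(nxt$type, "GT")
  expect_identical(nxt$flags[c("x", "z")], list(x = 0L, z = "b"))

  # GT after coordination, failed coordination triggers permanent retaliation
  nxt <- automaton_transition("GT", list(x = 1L, y = NA, z = "w"), "BoS", "C")
  expect_identical(nxt$type, "AD")

  # TfT with coordination on record: failed coordination retaliates one round,
  # cancels the record, alternates
  nxt <- automaton_transition("TfT", list(x = 1L, y = 0L, z = "w"), "BoS", "C")
  expect_identical(nxt$flags, list(x = 0L, y = 1L, z = "b"))

  # retaliating TfT plays Best; participant C coordinates on it, exiting
  # retaliation and restoring the record
  nxt <- automaton_transition("TfT", list(x = 0L, y = 1L, z = "b"), "BoS", "C")
  expect_identical(nxt$flags, list(x = 1L, y = 0L, z = "w"))
})

test_that("GT absorption into the AD block is permanent", {
  state <- automaton_transition("GT", automaton_initial_flags("GT"), "PD", "A")
  expect_identical(state$type, "AD")
  set.seed(42)
  for (i in 1:20) {
    g <- sample(GAMES, 1)
    expect_identical(automaton_behavior(state$type, state$flags, g), "A")
    state <- automaton_transition(state$type, state$flags, g,
                                  sample(ACTIONS, 1))
    expect_identical(state$type, "AD")
  }
})

test_that("TfT retaliation lasts exactly one round", {
  spec <- automaton_spec("TfT")
  ret <- spec$states[spec$states$y == 1L, ]
  for (i in seq_len(nrow(ret))) {
    fl <- list(x = ret$x[i], y = ret$y[i], z = ret$z[i])
    # in BoS the retaliating automaton plays A; participant C coordinates
    nxt <- automaton_transition("TfT", fl, "BoS", "C")
    expect_identical(nxt$flags$y, 0L)
    # in PD a cooperative participant ends the retaliation too
    nxt <- automaton_transition("TfT", fl, "PD", "C")
    expect_identical(nxt$flags$y, 0L)
  }
})

test_that("outside retaliation the BoS option alternates on every transition", {
  for (type in c("GT", "TfT")) {
    spec <- automaton_spec(type)
    st <- spec$states[is.na(spec$states$y) | spec$states$y == 0L, ]
    for (i in seq_len(nrow(st))) for (a in ACTIONS) {
      fl <- list(x = st$x[i], y = st$y[i], z = st$z[i])
      nxt <- automaton_transition(type, fl, "BoS", a)
      if (nxt$type == type)
        expect_false(nxt$flags$z == fl$z)
    }
  }
})

test_that("roster maps six named players onto the three types, two each", {
  pl <- default_players()
  expect_identical(nrow(pl), 6L)
  expect_identical(as.vector(table(pl$type)[AUTOMATON_TYPES]),
                   as.integer(c(2, 2, 2)))
  expect_false(anyDuplicated(pl$name) > 0)
})
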