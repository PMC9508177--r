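#' Opponent automata
#'
#' The three opponent strategies are finite-state automata
#' `M = (Omega, f, tau, x0)`:
#'
#' * **AD** (Always Defect): a single internal state; plays `A` in both games.
#' * **GT** (Grim Trigger): cooperates (plays `C` in PD, alternates between
#'   its Best and Worst options in BoS) until provoked, then retaliates
#'   forever. A provocation is a participant `A` in PD, or a failed BoS
#'   coordination after coordination has already occurred in the relationship.
#'   A retaliating GT behaves exactly like AD and never recovers, so the
#'   engine canonicalizes retaliating GT to the AD state block.
#' * **TfT** (Tit-for-Tat): same triggers as GT, but retaliation lasts one
#'   round, after which the automaton reverts to cooperative play.
#'
#' Internal flags:
#' * `x` (0/1): whether a BoS coordination has occurred with this partner;
#' * `y` (0/1): whether the automaton is retaliating (stored for TfT only;
#'   GT's retaliation is the AD block, AD has no flags);
#' * `z` (`"b"`/`"w"`): the option (Best/Worst) the automaton will play the
#'   next time the game is BoS. Outside retaliation the automaton plays `z`
#'   and then switches to the option it did not just play.
#'
#' In BoS the automaton's Best option is the abstract action `A` and its
#' Worst option is `C`; the players coordinate exactly when their abstract
#' actions differ.
#'
#' @name automata
NULL

.sentinel_flags <- function() list(x = NA_integer_, y = NA_integer_, z = NA_character_)

#' Construct an automaton specification
#'
#' Bundles the behavior rule, transition rule and initial condition of one
#' opponent type.
#'
#' @param type `"AD"`, `"GT"` or `"TfT"`.
#' @param name optional display name of the virtual player using this type.
#' @return An object of class `automaton_spec` with fields `type`, `name`,
#'   `n_internal_states`, and `states` (a data frame of the valid flag
#'   combinations).
#' @export
automaton_spec <- function(type = c("AD", "GT", "TfT"), name = NULL) {
  type <- match.arg(type)
  states <- switch(type,
    AD = data.frame(x = NA_integer_, y = NA_integer_, z = NA_character_),
    GT = expand.grid(x = 0:1, y = NA_integer_, z = c("b", "w"),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    TfT = expand.grid(x = 0:1, y = 0:1, z = c("b", "w"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  )
  structure(
    list(type = type, name = if (is.null(name)) type else name,
         n_internal_states = nrow(states), states = states),
    class = "automaton_spec"
  )
}

#' @export
print.automaton_spec <- function(x, ...) {
  cat(sprintf("<automaton_spec> %s (%s), %d internal flag state(s)\n",
              x$type, x$name, x$n_internal_states))
  invisible(x)
}

.check_flags <- function(type, flags) {
  stopifnot(is.list(flags), all(c("x", "y", "z") %in% names(flags)))
  bad <- function(what) {
    stop(sprintf("invalid flag '%s' (= %s) for automaton type %s",
                 what, format(flags[[what]]), type), call. = FALSE)
  }
  if (type == "AD") {
    if (!is.na(flags$x)) bad("x")
    if (!is.na(flags$y)) bad("y")
    if (!is.na(flags$z)) bad("z")
  } else if (type == "GT") {
    if (is.na(flags$x) || !flags$x %in% 0:1) bad("x")
    if (!is.na(flags$y)) bad("y")  # retaliation is the AD block, not a flag
    if (is.na(flags$z) || !flags$z %in% c("b", "w")) bad("z")
  } else {
    if (is.na(flags$x) || !flags$x %in% 0:1) bad("x")
    if (is.na(flags$y) || !flags$y %in% 0:1) bad("y")
    if (is.na(flags$z) || !flags$z %in% c("b", "w")) bad("z")
  }
  invisible(TRUE)
}

.type_of <- function(spec) if (inherits(spec, "automaton_spec")) spec$type else match.arg(spec, AUTOMATON_TYPES)

#' Automaton rule of behavior
#'
#' The function `f(omega, g)` giving the automaton's action in the current
#' stage game.
#'
#' @param spec an [automaton_spec()] or a type string.
#' @param flags internal flags, as returned by [automaton_initial_flags()] or
#'   [automaton_transition()].
#' @param game the current stage game, `"PD"` or `"BoS"`.
#' @return `"C"` or `"A"`.
#' @examples
#' automaton_behavior("AD", automaton_initial_flags("AD"), "PD")  # "A"
#' automaton_behavior("GT", list(x = 0L, y = NA, z = "b"), "PD")  # "C"
#' @export
automaton_behavior <- function(spec, flags, game) {
  type <- .type_of(spec)
  game <- match.arg(game, GAMES)
  .check_flags(type, flags)
  if (type == "AD") return("A")
  if (type == "TfT" && flags$y == 1L) return("A")
  if (game == "PD") return("C")
  ## BoS, not retaliating: play the stored next option (Best = A, Worst = C)
  if (flags$z == "b") "A" else "C"
}

#' Automaton state transition
#'
#' The function `tau(omega, g, a)` updating the internal state given the
#' stage game just played and the participant's action. For GT, entering
#' retaliation returns the absorbing AD-equivalent state (type `"AD"`).
#'
#' @inheritParams automaton_behavior
#' @param action the participant's action, `"C"` or `"A"`.
#' @return A list with fields `type` (possibly collapsed to `"AD"` for a
#'   retaliating GT) and `flags`.
#' @export
automaton_transition <- function(spec, flags, game, action) {
  type <- .type_of(spec)
  game <- match.arg(game, GAMES)
  action <- match.arg(action, ACTIONS)
  .check_flags(type, flags)

  if (type == "AD") return(list(type = "AD", flags = .sentinel_flags()))

  r <- automaton_behavior(type, flags, game)

  if (type == "GT") {
    if (game == "PD") {
      if (action == "A") return(list(type = "AD", flags = .sentinel_flags()))
      return(list(type = "GT", flags = flags))
    }
    ## BoS: coordination iff the abstract actions differ
    coord <- action != r
    if (!coord && flags$x == 1L)  # coordination had occurred, now failed
      return(list(type = "AD", flags = .sentinel_flags()))
    list(type = "GT",
         flags = list(x = as.integer(max(flags$x, coord)), y = NA_integer_,
                      z = .other_z(flags$z)))
  } else {  # TfT
    if (game == "PD") {
      if (action == "A")
        return(list(type = "TfT", flags = list(x = 0L, y = 1L, z = flags$z)))
      return(list(type = "TfT", flags = list(x = flags$x, y = 0L, z = flags$z)))
    }
    coord <- action != r
    trigger <- !coord && flags$x == 1L
    ## next BoS option is the one the automaton did not just play
    z_next <- if (r == "A") "w" else "b"
    list(type = "TfT",
         flags = list(
           x = if (trigger) 0L else as.integer(max(flags$x, coord)),
           y = as.integer(trigger),
           z = z_next))
  }
}

.other_z <- function(z) if (z == "b") "w" else "b"

#' Automaton initial condition
#'
#' The internal flags `x0` at the start of a relationship (a new partner):
#' AD has no flags; GT starts at `x = 0, z = "b"` (it opens BoS with its Best
#' option); TfT starts at `x = 0, y = 0, z = "w"` (it opens BoS with its
#' Worst option).
#'
#' @inheritParams automaton_behavior
#' @param game the stage game active when the relationship starts (the flags
#'   do not depend on it; accepted for interface symmetry).
#' @return An internal-flags list.
#' @export
automaton_initial_flags <- function(spec, game = NULL) {
  type <- .type_of(spec)
  switch(type,
    AD = .sentinel_flags(),
    GT = list(x = 0L, y = NA_integer_, z = "b"),
    TfT = list(x = 0L, y = 0L, z = "w")
  )
}

#' Default roster of virtual players
#'
#' Six named virtual players, two per automaton type, mirroring the design in
#' which each opponent strategy is carried by two stable personal names.
#'
#' @return A data frame with columns `name` and `type`.
#' @export
default_players <- function() {
  data.frame(
    name = c("Anna", "Aldo", "Greta", "Gerd", "Tina", "Timo"),
    type = rep(AUTOMATON_TYPES, each = 2),
    stringsAsFactors = FALSE
  )
}
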