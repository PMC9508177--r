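#' Strategic-complexity partial order and net-dominance index
#'
#' The complexity of the environment a player faces is determined by the
#' opponent's strategy and the active stage game. Two componentwise rankings
#' are assumed: over strategies, `TfT > GT > AD` (more internal states to
#' track); over games, `BoS > PD` (coordination requires alternation,
#' cooperation a constant action). Against AD the two games are equally
#' complex, so `(AD, PD)` and `(AD, BoS)` are equivalent. The transitive
#' closure of these relations is a partial order on the six
#' `(strategy, game)` pairs; some pairs, e.g. `(TfT, PD)` and `(GT, BoS)`,
#' remain incomparable. The complexity index of a vertex is the number of
#' vertices it strictly dominates minus the number that strictly dominate
#' it; equivalent vertices neither dominate nor are dominated by each other.
#'
#' @return `build_order()` returns an object of class `complexity_table`:
#'   list with `vertices` (data frame `theta`, `game`, `label`, `score`),
#'   `dominates` (6 x 6 logical matrix of the strict relation, rows dominate
#'   columns), `geq` (the reflexive-transitive relation), and `equivalences`.
#' @examples
#' ct <- build_order()
#' ct$vertices[, c("label", "score")]
#' @export
build_order <- function() {
  v <- expand.grid(game = GAMES, theta = AUTOMATON_TYPES,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  v <- v[, c("theta", "game")]
  v$label <- paste0("(", v$theta, ",", v$game, ")")
  n <- nrow(v)
  th_rank <- match(v$theta, AUTOMATON_TYPES)   # AD < GT < TfT
  g_rank <- match(v$game, GAMES)               # PD < BoS

  ## generators: componentwise weak dominance, plus the AD-pair equivalence
  geq <- outer(seq_len(n), seq_len(n), function(i, j)
    th_rank[i] >= th_rank[j] & g_rank[i] >= g_rank[j])
  ad <- which(v$theta == "AD")
  geq[ad[1], ad[2]] <- TRUE
  geq[ad[2], ad[1]] <- TRUE

  geq <- .transitive_closure(geq)

  equiv <- geq & t(geq)
  strict <- geq & !t(geq)
  dimnames(strict) <- dimnames(geq) <- dimnames(equiv) <-
    list(v$label, v$label)

  v$score <- as.integer(rowSums(strict) - colSums(strict))
  v$dominated_set <- apply(strict, 1, function(r)
    paste(v$label[r], collapse = ";"))
  v$dominating_set <- apply(strict, 2, function(r)
    paste(v$label[r], collapse = ";"))
  rownames(v) <- v$label

  structure(list(vertices = v, dominates = strict, geq = geq,
                 equivalences = equiv & !diag(n)),
            class = "complexity_table")
}

## boolean matrix transitive closure (repeated squaring; 6 nodes)
.transitive_closure <- function(R) {
  diag(R) <- TRUE
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) return(R2)
    R <- R2
  }
}

#' @export
print.complexity_table <- function(x, ...) {
  cat("<complexity_table> net-dominance scores over (strategy, game) pairs\n")
  print(x$vertices[, c("label", "score")], row.names = FALSE)
  invisible(x)
}

#' Complexity index of an environment
#'
#' Looks up the net-dominance score of one or more `(strategy, game)` pairs.
#'
#' @param theta automaton type(s), `"AD"`, `"GT"` or `"TfT"`.
#' @param game stage game(s), `"PD"` or `"BoS"`.
#' @param table a [build_order()] result (rebuilt if omitted).
#' @return Integer score(s).
#' @examples
#' complexity("TfT", "BoS")  # 5, the most complex environment
#' complexity("AD", "PD") == complexity("AD", "BoS")
#' @export
complexity <- function(theta, game, table = build_order()) {
  stopifnot(inherits(table, "complexity_table"))
  lab <- paste0("(", theta, ",", game, ")")
  i <- match(lab, table$vertices$label)
  if (anyNA(i)) stop("unknown (strategy, game) pair", call. = FALSE)
  table$vertices$score[i]
}

#' Is one environment more complex than another?
#'
#' Strict dominance in the transitive closure; returns `FALSE` both for the
#' reverse relation and for incomparable pairs (use [comparable()] to
#' distinguish them).
#'
#' @param theta1,game1,theta2,game2 the two pairs.
#' @param table a [build_order()] result.
#' @export
dominates <- function(theta1, game1, theta2, game2, table = build_order()) {
  l1 <- paste0("(", theta1, ",", game1, ")")
  l2 <- paste0("(", theta2, ",", game2, ")")
  unname(table$dominates[l1, l2])
}

#' @rdname dominates
#' @export
comparable <- function(theta1, game1, theta2, game2, table = build_order()) {
  l1 <- paste0("(", theta1, ",", game1, ")")
  l2 <- paste0("(", theta2, ",", game2, ")")
  unname(table$geq[l1, l2] || table$geq[l2, l1])
}

#' Complexity score per environment state
#'
#' @param table a [build_order()] result.
#' @return Named integer vector over the 26 canonical state labels.
#' @export
state_complexity <- function(table = build_order()) {
  s <- .states()
  out <- complexity(s$theta, s$game, table)
  names(out) <- s$label
  out
}

#' Tabular export of the complexity table
#'
#' @param x a `complexity_table`.
#' @param row.names,optional,... S3 compatibility (unused).
#' @export
as.data.frame.complexity_table <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(x$vertices[, c("label", "theta", "game", "score",
                            "dominated_set", "dominating_set")],
             stringsAsFactors = FALSE, row.names = row.names)
}
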