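#' Score a trial log against the model
#'
#' Annotates each trial with its per-trial loss `L(s, a)` and the complexity
#' index of its environment, and computes per-subject total losses. The log
#' is first validated against the automaton engine (see
#' [validate_trial_log()]); an inconsistent log is rejected with the
#' coordinates of the first mismatch.
#'
#' @param trials a trial-log data frame (from [play_session()],
#'   [generate_cohort()]`$trials`, or [read_trial_log()]), or a `cohort`.
#' @param solution a [solve_values()] result.
#' @param table a [build_order()] complexity table.
#' @param validate set `FALSE` to skip the replay validation.
#' @return An object of class `scored_dataset`: list with `trials` (the log
#'   with `loss`, `complexity` and `optimal` filled), `subject_totals`
#'   (data frame `subject`, `total_loss`, `n_trials`, `pct_optimal`) and
#'   `pct_optimal` (overall % of trials choosing an optimal action).
#' @export
score_dataset <- function(trials, solution = solve_values(),
                          table = build_order(), validate = TRUE) {
  if (inherits(trials, "cohort")) trials <- trials$trials
  stopifnot(inherits(solution, "value_solution"))
  if (validate) validate_trial_log(trials)
  idx <- .resolve_state(trials$state)
  k <- match(trials$action, ACTIONS)
  trials$loss <- unname(solution$L[cbind(idx, k)])
  ## complexity is a property of the faced condition (opponent strategy x
  ## game), so a retaliating GT still counts as a GT environment
  trials$complexity <- complexity(trials$theta, trials$game, table)
  tie_tol <- 1e-9
  trials$optimal <- trials$loss <= tie_tol
  agg <- stats::aggregate(cbind(total_loss = loss, optimal = optimal) ~ subject,
                          data = trials, FUN = sum)
  nsub <- stats::aggregate(loss ~ subject, data = trials, FUN = length)
  totals <- data.frame(subject = agg$subject, total_loss = agg$total_loss,
                       n_trials = nsub$loss,
                       pct_optimal = 100 * agg$optimal / nsub$loss,
                       stringsAsFactors = FALSE)
  structure(list(trials = trials, subject_totals = totals,
                 pct_optimal = 100 * mean(trials$optimal)),
            class = "scored_dataset")
}

#' @export
print.scored_dataset <- function(x, ...) {
  cat(sprintf(
    "<scored_dataset> %d trials, %d subjects; %.1f%% optimal choices; total loss %.3f\n",
    nrow(x$trials), nrow(x$subject_totals), x$pct_optimal,
    sum(x$trials$loss)))
  invisible(x)
}

.subset_trials <- function(trials, which = c("all", "change", "no_change")) {
  which <- match.arg(which)
  switch(which,
    all = trials,
    change = trials[trials$change_type != "none", , drop = FALSE],
    no_change = trials[trials$change_type == "none", , drop = FALSE])
}

#' Regress loss or RT on environment complexity
#'
#' The central behavioral regressions: per-trial loss (or RT) on the
#' complexity index, with the non-independence of trials within subject
#' handled either by cluster-robust standard errors on an OLS fit (default)
#' or by a subject-level random intercept (`method = "mixed"`, lme4). With
#' `with_groups = TRUE` the model adds ability-group main effects and
#' group x complexity interactions (treatment coding, reference `"low"`, so
#' the `complexity:groupX` coefficients estimate how much flatter the
#' complexity effect is in group X than in the low group).
#'
#' For the clustered fit, each coefficient is tested with a cluster-robust
#' Wald chi-square statistic (`(estimate/se)^2`) whose p-value is computed
#' from a t distribution with G - 1 degrees of freedom (G = number of
#' subjects). For the mixed fit, the complexity effect is additionally
#' tested with a likelihood-ratio chi-square against the model without it.
#'
#' @param data a `scored_dataset` (or a data frame with columns `loss`/`rt`,
#'   `complexity`, `subject`, and `group` when `with_groups = TRUE`).
#' @param with_groups add group main effects and group x complexity
#'   interactions.
#' @param trials `"all"`, `"change"` (game or partner changed on the trial)
#'   or `"no_change"`.
#' @param method `"clustered"` (OLS + cluster-robust errors) or `"mixed"`
#'   (random intercept per subject).
#' @return An object of class `complexity_fit`: list with `coefficients`
#'   (data frame `term`, `estimate`, `std_error`, `chisq`, `p_value`),
#'   `outcome`, `method`, `n_trials`, `n_subjects`, `fit` (the underlying
#'   model object) and, for `method = "mixed"`, `lrt` (the likelihood-ratio
#'   test of the complexity effect).
#' @export
fit_loss_model <- function(data, with_groups = FALSE,
                           trials = c("all", "change", "no_change"),
                           method = c("clustered", "mixed")) {
  .fit_behavior(data, "loss", with_groups, match.arg(trials),
                match.arg(method))
}

#' @rdname fit_loss_model
#' @export
fit_rt_model <- function(data, with_groups = FALSE,
                         trials = c("all", "change", "no_change"),
                         method = c("clustered", "mixed")) {
  .fit_behavior(data, "rt", with_groups, match.arg(trials),
                match.arg(method))
}

.fit_behavior <- function(data, outcome, with_groups, trials, method) {
  df <- if (inherits(data, "scored_dataset")) data$trials else data
  df <- .subset_trials(df, trials)
  need <- c(outcome, "complexity", "subject", if (with_groups) "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[stats::complete.cases(df[, need]), , drop = FALSE]
  if (length(unique(df$complexity)) < 2L)
    stop("degenerate design: a single complexity level", call. = FALSE)
  if (length(unique(df$subject)) < 2L)
    stop("need at least two subjects", call. = FALSE)
  if (with_groups)
    df$group <- factor(df$group, levels = c("low", "medium", "high"))

  fml <- stats::as.formula(paste(
    outcome, "~", if (with_groups) "complexity * group" else "complexity"))
  G <- length(unique(df$subject))

  if (method == "clustered") {
    fit <- stats::lm(fml, data = df)
    V <- sandwich::vcovCL(fit, cluster = df$subject, type = "HC1")
    ct <- lmtest::coeftest(fit, vcov. = V, df = G - 1)
    coefs <- data.frame(term = rownames(ct),
                        estimate = ct[, 1], std_error = ct[, 2],
                        chisq = ct[, 3]^2, p_value = ct[, 4],
                        stringsAsFactors = FALSE, row.names = NULL)
    lrt <- NULL
  } else {
    full <- lme4::lmer(stats::as.formula(paste(
      outcome, "~", if (with_groups) "complexity * group" else "complexity",
      "+ (1 | subject)")), data = df, REML = FALSE)
    red <- lme4::lmer(stats::as.formula(paste(
      outcome, "~", if (with_groups) "group" else "1", "+ (1 | subject)")),
      data = df, REML = FALSE)
    an <- stats::anova(red, full)
    lrt <- list(chisq = an$Chisq[2], df = an$Df[2],
                p_value = an$`Pr(>Chisq)`[2])
    cf <- summary(full)$coefficients
    coefs <- data.frame(term = rownames(cf),
                        estimate = cf[, 1], std_error = cf[, 2],
                        chisq = (cf[, 1] / cf[, 2])^2,
                        p_value = 2 * stats::pt(abs(cf[, 3]), df = G - 1,
                                                lower.tail = FALSE),
                        stringsAsFactors = FALSE, row.names = NULL)
    fit <- full
  }
  structure(list(coefficients = coefs, outcome = outcome, method = method,
                 with_groups = with_groups, trials = trials,
                 n_trials = nrow(df), n_subjects = G, fit = fit, lrt = lrt),
            class = "complexity_fit")
}

#' @export
print.complexity_fit <- function(x, ...) {
  cat(sprintf("<complexity_fit> %s ~ complexity%s (%s; %s trials; %d trials, %d subjects)\n",
              x$outcome, if (x$with_groups) " * group" else "",
              x$method, x$trials, x$n_trials, x$n_subjects))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4),
                  std_error = signif(std_error, 3),
                  chisq = signif(chisq, 4),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  if (!is.null(x$lrt))
    cat(sprintf("LR test of complexity: chisq(%d) = %.2f, p = %.3g\n",
                x$lrt$df, x$lrt$chisq, x$lrt$p_value))
  invisible(x)
}

#' Extract the test of one model term
#'
#' @param fit a `complexity_fit`.
#' @param term coefficient name (default the complexity main effect).
#' @return A one-row data frame with `estimate`, `std_error`, `chisq`,
#'   `p_value`.
#' @export
effect_test <- function(fit, term = "complexity") {
  stopifnot(inherits(fit, "complexity_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (!nrow(row)) stop("no such term: ", term, call. = FALSE)
  row
}

#' Tertile split of ability scores
#'
#' Partitions subjects into low/medium/high groups at the 33rd and 66th
#' percentiles of their score distribution. A score tied with a cutoff goes
#' to the lower group. With heavily tied score distributions the groups can
#' be uneven.
#'
#' @param scores numeric vector of ability scores (one per subject).
#' @param labels group labels, low to high.
#' @return A factor of group labels, ordered low < medium < high.
#' @examples
#' table(assign_groups(1:42))  # 14 / 14 / 14
#' @export
assign_groups <- function(scores, labels = c("low", "medium", "high")) {
  if (length(scores) < 3L)
    stop("need at least three subjects for a tertile split", call. = FALSE)
  if (length(unique(scores)) == 1L)
    stop("degenerate score distribution: all scores equal", call. = FALSE)
  cuts <- stats::quantile(scores, c(0.33, 0.66), names = FALSE)
  g <- ifelse(scores <= cuts[1], labels[1],
       ifelse(scores <= cuts[2], labels[2], labels[3]))
  factor(g, levels = labels, ordered = TRUE)
}

#' Mean loss and RT by group and complexity level
#'
#' Cell means underlying the marginal-effects plot.
#'
#' @param scored a `scored_dataset` whose trials carry a `group` column.
#' @return A data frame `group`, `complexity`, `mean_loss`, `mean_rt`, `n`.
#' @export
complexity_profile <- function(scored) {
  df <- if (inherits(scored, "scored_dataset")) scored$trials else scored
  stopifnot(all(c("group", "complexity", "loss") %in% names(df)))
  sp <- split(df, list(df$group, df$complexity), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    group = d$group[1], complexity = d$complexity[1],
    mean_loss = mean(d$loss),
    mean_rt = if (all(is.na(d$rt))) NA_real_ else mean(d$rt, na.rm = TRUE),
    n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$group, out$complexity), ]
}

#' Plot loss / RT against complexity by ability group
#'
#' Base-graphics plot of the cell means from [complexity_profile()].
#'
#' @param scored a `scored_dataset` with a `group` column.
#' @param outcome `"loss"` or `"rt"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_complexity_effects <- function(scored, outcome = c("loss", "rt"), ...) {
  outcome <- match.arg(outcome)
  prof <- complexity_profile(scored)
  col <- if (outcome == "loss") "mean_loss" else "mean_rt"
  wide <- stats::reshape(prof[, c("group", "complexity", col)],
                         idvar = "complexity", timevar = "group",
                         direction = "wide")
  wide <- wide[order(wide$complexity), ]
  graphics::matplot(wide$complexity, wide[, -1], type = "b", pch = 16,
                    lty = 1, xlab = "complexity index",
                    ylab = if (outcome == "loss")
                      "mean per-trial loss (per-period ECU)" else "mean RT (ms)",
                    ...)
  graphics::legend("topleft", legend = sub(paste0(col, "\\."), "",
                                           colnames(wide)[-1]),
                   col = seq_len(ncol(wide) - 1), pch = 16, lty = 1,
                   bty = "n")
  invisible(wide)
}
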