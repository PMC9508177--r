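test_that("scoring an optimal-policy log yields all-zero losses", {
  sol <- shared_solution(); ct <- shared_order()
  sq <- generate_sequence(sequence_config(seed = 31, n_runs = 2L))
  log <- play_session(sq, optimal_agent(sol))
  scored <- score_dataset(log, sol, ct)
  expect_true(all(scored$trials$loss == 0))
  expect_equal(scored$pct_optimal, 100)
  expect_equal(scored$subject_totals$total_loss, 0)
})

test_that("a single suboptimal choice is charged exactly the solver loss", {
  sol <- shared_solution(); ct <- shared_order()
  seqdf <- data.frame(run = 1L, trial = 1:10, change_type = "none",
                      opponent = "Anna", theta = "AD", game = "PD",
                      stringsAsFactors = FALSE)
  n <- 0L
  agent <- function(s) { n <<- n + 1L; if (n == 4L) "C" else "A" }
  log <- play_session(seqdf, agent)
  scored <- score_dataset(log, sol, ct)
  pos <- which(scored$trials$loss > 0)
  expect_identical(pos, 4L)
  expect_equal(scored$trials$loss[4], score_loss("AD:PD", "C", sol))
  expect_equal(scored$pct_optimal, 90)
  expect_equal(scored$subject_totals$total_loss,
               score_loss("AD:PD", "C", sol))
})

test_that("scoring is invariant to row order and additive over runs", {
  sol <- shared_solution(); ct <- shared_order()
  co <- generate_cohort(small_cohort_config(seed = 32), sol, ct)
  scored <- score_dataset(co, sol, ct)
  set.seed(1)
  perm <- sample(nrow(co$trials))
  scored_p <- score_dataset(co$trials[perm, ], sol, ct)
  t1 <- scored$subject_totals[order(scored$subject_totals$subject), ]
  t2 <- scored_p$subject_totals[order(scored_p$subject_totals$subject), ]
  expect_equal(t1$total_loss, t2$total_loss)
  # additivity: per-run sums add up to the subject total
  tr <- scored$trials
  per_run <- tapply(tr$loss, list(tr$subject, tr$run), sum)
  expect_equal(unname(rowSums(per_run)), t1$total_loss)
})

test_that("inconsistent logs are rejected with trial coordinates", {
  sol <- shared_solution(); ct <- shared_order()
  sq <- generate_sequence(sequence_config(seed = 33, n_runs = 1L))
  log <- play_session(sq, optimal_agent(sol), subject = "S2")
  log$action[10] <- setdiff(ACTIONS, log$action[10])  # payoff now stale
  expect_error(score_dataset(log, sol, ct), "S2, run 1, trial 10")
})

test_that("tertile assignment splits at the 33rd and 66th percentiles", {
  g <- assign_groups(1:42)
  expect_identical(as.vector(table(g)), as.integer(c(14, 14, 14)))
  expect_identical(as.character(g[1]), "low")
  expect_identical(as.character(g[42]), "high")
  # ties at a cutoff go to the lower group
  scores <- c(1, 2, 2, 2, 5, 6, 7, 8, 9)
  g2 <- assign_groups(scores)
  expect_true(all(g2[scores == 2] == "low"))
  expect_error(assign_groups(rep(3, 10)), "degenerate")
  expect_error(assign_groups(c(1, 2)), "at least three")
  # a tied Raven-like distribution can produce uneven groups
  set.seed(9)
  ab <- round(rnorm(42, 20, 4))
  expect_identical(sum(table(assign_groups(ab))), 42L)
})

test_that("a flat error rate leaves only the structural loss gradient", {
  # With the complexity slope of the error link set to zero, errors are
  # equally frequent everywhere, but an error in a more complex environment
  # still costs more (L of the suboptimal action grows with complexity), so
  # a reduced but genuinely positive loss-complexity slope remains.
  sol <- shared_solution(); ct <- shared_order()
  cfg <- cohort_config(beta = c(low = 0, medium = 0, high = 0), seed = 34)
  scored <- score_dataset(generate_cohort(cfg, sol, ct), sol, ct,
                          validate = FALSE)
  est <- effect_test(fit_loss_model(scored), "complexity")
  expect_gt(est$estimate, 0)
  expect_lt(est$estimate, 0.07)  # well below the default-generator ~0.11
  # the analytic curve predicts the same residual gradient
  curve <- expected_loss_curve(cfg, sol, ct)
  lowc <- curve[curve$group == "low", ]
  expect_true(all(diff(lowc$expected_loss) > 0))
})

test_that("the clustered complexity test is calibrated under its model null", {
  # Engine sanity: on outcomes simulated from the null random-intercept
  # model (subject effects + residual noise, no complexity dependence) over
  # the real cohort design, the nominal-5% complexity test rejects at close
  # to 5%.
  sol <- shared_solution(); ct <- shared_order()
  scored <- score_dataset(generate_cohort(cohort_config(seed = 41), sol, ct),
                          sol, ct, validate = FALSE)
  df <- scored$trials
  m0 <- lme4::lmer(loss ~ (1 | subject), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m0))
  sd_between <- vc$sdcor[1]; sd_within <- vc$sdcor[2]
  subs <- unique(df$subject)
  set.seed(4242)
  rejections <- 0L
  for (r in 1:200) {
    u <- rnorm(length(subs), 0, sd_between)
    df$loss <- mean(scored$trials$loss) + u[match(df$subject, subs)] +
      rnorm(nrow(df), 0, sd_within)
    p <- effect_test(fit_loss_model(df), "complexity")$p_value
    rejections <- rejections + (p < 0.05)
  }
  expect_lte(rejections / 200, 0.07)
})

test_that("the default cohort shows the generated loss structure", {
  sol <- shared_solution(); ct <- shared_order()
  scored <- score_dataset(generate_cohort(cohort_config(seed = 35), sol, ct),
                          sol, ct, validate = FALSE)
  fit <- fit_loss_model(scored)
  est <- effect_test(fit, "complexity")
  expect_gt(est$estimate, 0)
  expect_lt(est$p_value, 0.05)
  fitg <- fit_loss_model(scored, with_groups = TRUE)
  # low group (reference) is hit harder by complexity than the high group
  expect_lt(effect_test(fitg, "complexity:grouphigh")$estimate, 0)
  # subsetting by change type works and keeps the positive effect
  fit_chg <- fit_loss_model(scored, trials = "change")
  fit_stay <- fit_loss_model(scored, trials = "no_change")
  expect_gt(effect_test(fit_chg, "complexity")$estimate, 0)
  expect_gt(effect_test(fit_stay, "complexity")$estimate, 0)
})

test_that("RT slope is recovered within two standard errors", {
  sol <- shared_solution(); ct <- shared_order()
  cfg <- cohort_config(seed = 36)
  scored <- score_dataset(generate_cohort(cfg, sol, ct), sol, ct,
                          validate = FALSE)
  fit <- fit_rt_model(scored)
  est <- effect_test(fit, "complexity")
  cx <- state_complexity(ct)
  generating <- cfg$rt_slope / diff(range(cx))  # ms per complexity unit
  expect_lt(abs(est$estimate - generating), 2 * est$std_error)
  expect_lt(est$p_value, 0.05)
  # RT intercepts are group-constant by default: no group interaction
  fitg <- fit_rt_model(scored, with_groups = TRUE)
  for (term in c("complexity:groupmedium", "complexity:grouphigh")) {
    it <- effect_test(fitg, term)
    expect_lt(abs(it$estimate), 5)
    expect_gt(it$p_value, 0.001)
  }
})

test_that("a zero-slope RT generator yields a near-zero fitted slope", {
  sol <- shared_solution(); ct <- shared_order()
  cfg <- small_cohort_config(seed = 37, rt_slope = 0)
  scored <- score_dataset(generate_cohort(cfg, sol, ct), sol, ct,
                          validate = FALSE)
  est <- effect_test(fit_rt_model(scored), "complexity")
  expect_lt(abs(est$estimate), 3 * est$std_error + 1e-9)
})

test_that("clustered and random-intercept fits agree on the default cohort", {
  sol <- shared_solution(); ct <- shared_order()
  scored <- score_dataset(generate_cohort(cohort_config(seed = 38), sol, ct),
                          sol, ct, validate = FALSE)
  f_cl <- fit_loss_model(scored, method = "clustered")
  f_mx <- fit_loss_model(scored, method = "mixed")
  e_cl <- effect_test(f_cl, "complexity")
  e_mx <- effect_test(f_mx, "complexity")
  expect_identical(sign(e_cl$estimate), sign(e_mx$estimate))
  expect_lt(e_cl$p_value, 0.05)
  expect_lt(e_mx$p_value, 0.05)
  expect_lt(f_mx$lrt$p_value, 0.05)
  expect_equal(e_cl$estimate, e_mx$estimate, tolerance = 0.05)
})

test_that("degenerate regression designs are rejected", {
  sol <- shared_solution(); ct <- shared_order()
  co <- generate_cohort(small_cohort_config(seed = 39), sol, ct)
  scored <- score_dataset(co, sol, ct, validate = FALSE)
  one_level <- scored$trials[scored$trials$theta == "AD", ]
  expect_error(fit_loss_model(one_level), "single complexity level")
  one_subject <- scored$trials[scored$trials$subject == "S01", ]
  expect_error(fit_loss_model(one_subject), "two subjects")
  no_group <- scored$trials[, setdiff(names(scored$trials), "group")]
  expect_error(fit_loss_model(no_group, with_groups = TRUE), "group")
})

test_that("profiles and marginal-effect plots summarize group x complexity", {
  sol <- shared_solution(); ct <- shared_order()
  scored <- score_dataset(generate_cohort(small_cohort_config(seed = 40),
                                          sol, ct), sol, ct, validate = FALSE)
  prof <- complexity_profile(scored)
  expect_identical(nrow(prof), 12L)  # 3 groups x 4 levels
  expect_true(all(prof$n > 0))
  pdf(NULL)
  on.exit(dev.off())
  wide <- plot_complexity_effects(scored, "loss")
  expect_identical(nrow(wide), 4L)
})
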