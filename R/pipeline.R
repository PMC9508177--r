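#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: Nature's probabilities,
#' the solver tolerance, the sequence design and the cohort generator, plus
#' the root seed. Serializable to YAML and echoed into every output header,
#' so a run is reproducible from its artifacts.
#'
#' @param params a [nature_params()].
#' @param tol solver tolerance (sup norm).
#' @param sequence a [sequence_config()].
#' @param cohort a [cohort_config()].
#' @param seed root seed for the whole pipeline.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = nature_params(), tol = 1e-10,
                            sequence = sequence_config(),
                            cohort = cohort_config(sequence = sequence),
                            seed = 1L) {
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol <= 0)
    stop("solver tolerance must be a single positive number", call. = FALSE)
  structure(list(params = params, tol = tol, sequence = sequence,
                 cohort = cohort, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- .config_to_list(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  players <- do.call(rbind, lapply(x$sequence$players, function(p)
    data.frame(name = p$name, type = p$type, stringsAsFactors = FALSE)))
  sq <- sequence_config(
    mode = x$sequence$mode, run_length = x$sequence$run_length,
    composition = unlist(x$sequence$composition),
    n_runs = x$sequence$n_runs, players = players,
    xi = x$sequence$xi, rho = x$sequence$rho,
    allow_self_redraw = x$sequence$allow_self_redraw,
    seed = x$sequence$seed)
  co <- cohort_config(
    n_subjects = x$cohort$n_subjects,
    group_sizes = unlist(x$cohort$group_sizes),
    ability_mean = unlist(x$cohort$ability_mean),
    ability_sd = unlist(x$cohort$ability_sd),
    alpha = unlist(x$cohort$alpha), beta = unlist(x$cohort$beta),
    rt_intercept = unlist(x$cohort$rt_intercept),
    rt_slope = x$cohort$rt_slope, rt_sd = x$cohort$rt_sd,
    choice_model = x$cohort$choice_model,
    softmax_temp = unlist(x$cohort$softmax_temp),
    sequence = sq, seed = x$cohort$seed)
  pipeline_config(
    params = nature_params(x$params$delta, x$params$xi, x$params$rho),
    tol = x$tol, sequence = sq, cohort = co, seed = x$seed)
}

.config_to_list <- function(config) {
  sq <- config$sequence
  co <- config$cohort
  list(
    params = list(delta = config$params$delta, xi = config$params$xi,
                  rho = config$params$rho),
    tol = config$tol,
    seed = config$seed,
    sequence = list(
      mode = sq$mode, run_length = sq$run_length,
      composition = as.list(sq$composition), n_runs = sq$n_runs,
      players = lapply(seq_len(nrow(sq$players)), function(i)
        list(name = sq$players$name[i], type = sq$players$type[i])),
      xi = sq$xi, rho = sq$rho, allow_self_redraw = sq$allow_self_redraw,
      seed = sq$seed),
    cohort = list(
      n_subjects = co$n_subjects, group_sizes = as.list(co$group_sizes),
      ability_mean = as.list(co$ability_mean),
      ability_sd = as.list(co$ability_sd),
      alpha = as.list(co$alpha), beta = as.list(co$beta),
      rt_intercept = as.list(co$rt_intercept), rt_slope = co$rt_slope,
      rt_sd = co$rt_sd, choice_model = co$choice_model,
      softmax_temp = as.list(co$softmax_temp), seed = co$seed))
}

## cheap stable checksum of the config (hex), for output headers
.config_hash <- function(config) {
  s <- yaml::as.yaml(.config_to_list(config))
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2^28
  sprintf("%07x", h)
}

.stage_msg <- function(fmt, ..., t0 = NULL) {
  msg <- sprintf(fmt, ...)
  if (!is.null(t0))
    msg <- sprintf("%s [%.2fs]", msg, as.numeric(Sys.time()) - t0)
  message("[stratcomplex] ", msg)
}

#' Run the full analysis pipeline
#'
#' Solves the dynamic program, builds the complexity table, generates a
#' synthetic cohort, scores it, and fits the loss and RT regressions.
#' Artifacts are written as plain delimited text, each with a commented
#' header carrying the config hash and seed. Stages are run in order; a
#' failure leaves the artifacts of completed stages on disk and reports the
#' failing stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory artifacts: `solution`,
#'   `complexity`, `cohort`, `scored`, `fits` and the vector of file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) stop("'out_dir' is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  hdr <- list(package = "stratcomplex", config_hash = hash,
              seed = config$seed)
  paths <- character(0)
  stage <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    .stage_msg("stage %-10s done", name, t0 = t0)
    res
  }
  write_tsv <- function(df, file, extra = list()) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    h <- c(hdr, extra)
    writeLines(sprintf("# %s: %s", names(h), vapply(h, format, character(1))),
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, path)
    path
  }

  set.seed(config$seed)
  cohort_cfg <- config$cohort
  if (is.null(cohort_cfg$seed))
    cohort_cfg$seed <- sample.int(.Machine$integer.max, 1L)

  solution <- stage("solve", solve_values(config$params, tol = config$tol))
  write_tsv(as.data.frame(solution), "solution.tsv",
            list(delta = config$params$delta, xi = config$params$xi,
                 rho = config$params$rho, tol = config$tol))

  ctable <- stage("complexity", build_order())
  write_tsv(as.data.frame(ctable), "complexity.tsv")

  cohort <- stage("cohort", generate_cohort(cohort_cfg, solution, ctable))
  write_tsv(cohort$subjects, "subjects.tsv",
            list(cohort_seed = cohort_cfg$seed))
  write_tsv(cohort$trials, "trials.tsv", list(cohort_seed = cohort_cfg$seed))

  scored <- stage("score", score_dataset(cohort$trials, solution, ctable))
  write_tsv(scored$trials, "scored.tsv")
  write_tsv(scored$subject_totals, "subject_totals.tsv")

  fits <- stage("fit", list(
    loss = fit_loss_model(scored),
    loss_groups = fit_loss_model(scored, with_groups = TRUE),
    rt = fit_rt_model(scored),
    rt_groups = fit_rt_model(scored, with_groups = TRUE)))
  fit_path <- file.path(out_dir, "fits.txt")
  con <- file(fit_path, "w")
  writeLines(sprintf("# %s: %s", names(hdr),
                     vapply(hdr, format, character(1))), con)
  sink(con)
  for (nm in names(fits)) { cat("==", nm, "==\n"); print(fits[[nm]]); cat("\n") }
  sink()
  close(con)
  paths <- c(paths, fit_path)

  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  paths <- c(paths, file.path(out_dir, "config.yaml"))
  .stage_msg("pipeline complete: %d artifacts in %s", length(paths), out_dir)
  invisible(list(solution = solution, complexity = ctable, cohort = cohort,
                 scored = scored, fits = fits, paths = paths))
}
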