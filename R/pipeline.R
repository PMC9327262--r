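# End-to-end orchestration: simulate -> extract -> strategy -> analyze,
# with a serialisable run configuration so every output is reproducible
# from (config, seed) alone.

#' Assemble a pipeline run configuration
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_spec()].
#' @param steady_state A [steady_state_config()].
#' @param alpha,n_comparisons Significance settings for [analyze_cohort()].
#' @param include_samples Synthesize kinematic sample tables (needed for
#'   the kinematic parameters and strategy summaries; event-based
#'   parameters work without them).
#' @param out_dir Output directory; `NULL` disables file output.
#' @return A `run_config`.
#' @export
run_config <- function(task = oh_task(),
                       cohort = cohort_spec(50, global_seed = 1),
                       steady_state = steady_state_config(),
                       alpha = 0.05, n_comparisons = 68,
                       include_samples = TRUE,
                       out_dir = NULL) {
  cfg <- list(task = task, cohort = cohort, steady_state = steady_state,
              alpha = alpha, n_comparisons = n_comparisons,
              include_samples = include_samples, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' Flat YAML serialisation of every task, cohort, steady-state and
#' analysis field, so that a run can be archived alongside its outputs and
#' reproduced exactly.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (inherits(v, c("task_config", "cohort_spec",
                                            "steady_state_config")))
      strip(v) else v)
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  task <- do.call(task_config, raw$task)
  co <- raw$cohort
  co$age_range <- as.numeric(unlist(co$age_range))
  for (f in c("intercepts", "age_slopes", "sex_offsets", "between_subject_sd")) {
    co[[f]] <- unlist(co[[f]])
  }
  cohort <- do.call(cohort_spec, co)
  ss <- do.call(steady_state_config, raw$steady_state)
  run_config(task = task, cohort = cohort, steady_state = ss,
             alpha = raw$alpha, n_comparisons = raw$n_comparisons,
             include_samples = isTRUE(raw$include_samples),
             out_dir = raw$out_dir)
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, extracts the per-trial parameter battery (adding
#' in-sample task scores), computes strategy summaries (when kinematic
#' samples are available), and runs the cohort statistics. When
#' `config$out_dir` is set, writes the manifest, parameters and strategy
#' tables, the analysis tables and text report, and an archived copy of
#' the configuration. The run is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config A [run_config()].
#' @return List with `manifest`, `parameters` (cohort table), `strategy`,
#'   `analysis`, `ground_truth`, and `log` (character vector of run notes).
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(cohort = cohort_spec(8, global_seed = 3)))
#' res$analysis
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  note("simulate: %s task, %d participants x %d trial(s), seed %d",
       config$task$task_name, config$cohort$n_participants,
       config$cohort$trials_per_participant, config$cohort$global_seed)
  sim <- simulate_cohort(config$cohort, config$task,
                         include_samples = config$include_samples)

  note("extract: %d trials", length(sim$trials))
  params <- extract_all_parameters(sim$trials, sim$manifest,
                                   cfg = config$steady_state)
  flags <- params$steady_state_flag != "none"
  if (any(flags)) {
    note("extract: %d degenerate steady-state trial(s): %s", sum(flags),
         paste(unique(params$steady_state_flag[flags]), collapse = ", "))
  }
  cohort_tab <- build_cohort_table(sim$manifest, params)
  cohort_tab <- add_task_scores(cohort_tab)
  if (config$task$task_name == "OH") {
    note("extract: OHA-only parameters (distractor_proportion, "
         %+% "object_processing_rate) absent for OH")
  }

  strat <- NULL
  if (config$include_samples) {
    note("strategy: %d trials", length(sim$trials))
    strat <- do.call(rbind, lapply(sim$trials, strategy_summary))
  } else {
    note("strategy: skipped (no kinematic samples)")
  }

  note("analyze: alpha %g over %d comparisons", config$alpha,
       config$n_comparisons)
  analysis <- analyze_cohort(cohort_tab, alpha = config$alpha,
                             n_comparisons = config$n_comparisons)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_manifest(sim$manifest, file.path(config$out_dir, "manifest.csv"))
    write_parameters(cohort_tab, file.path(config$out_dir, "parameters.csv"))
    if (!is.null(strat)) {
      write_delim6(strat, file.path(config$out_dir, "strategy.csv"))
    }
    write_analysis(analysis, config$out_dir)
    write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
    note("outputs written to %s", config$out_dir)
  }

  list(manifest = sim$manifest, parameters = cohort_tab, strategy = strat,
       analysis = analysis, ground_truth = sim$ground_truth, log = log)
}

`%+%` <- function(a, b) paste0(a, b)
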