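# End-to-end orchestration: simulate or load a cohort, grade, classify
# outcomes, run the primary and sensitivity analyses and emit a
# structured report.

#' Pipeline run configuration
#'
#' @param input Path to a cohort CSV (see [read_cohort()]), or `NULL` to
#'   generate a synthetic cohort.
#' @param cohort A [cohort_config()] used when `input` is `NULL`.
#' @param grading A [grading_criteria()].
#' @param paso A [paso_criteria()].
#' @param level Confidence coefficient of the analyses.
#' @param margin Non-inferiority margin (must be negative).
#' @param bootstrap_reps Replicates of the AVS-failure bootstrap.
#' @param out_dir Directory for report files, or `NULL` to skip writing.
#' @param seed Integer seed driving every random stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, cohort = cohort_config(),
                       grading = grading_criteria(), paso = paso_criteria(),
                       level = 0.95, margin = -0.17, bootstrap_reps = 1e4,
                       out_dir = NULL, seed = 1L) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  if (margin >= 0) stop("non-inferiority 'margin' must be negative")
  structure(list(input = input, cohort = cohort, grading = grading,
                 paso = paso, level = level, margin = margin,
                 bootstrap_reps = bootstrap_reps, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `input`, `level`, `margin`,
#' `bootstrap_reps`, `out_dir`, `seed`, and nested `cohort`, `grading`,
#' `paso` blocks whose entries are passed to [cohort_config()],
#' [grading_criteria()] and [paso_criteria()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("input", "level", "margin",
                                  "bootstrap_reps", "out_dir", "seed"))]
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$grading)) args$grading <- do.call(grading_criteria, y$grading)
  if (!is.null(y$paso)) args$paso <- do.call(paso_criteria, y$paso)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages mirror the trial workflow: obtain a cohort (from file or the
#' generator), grade both investigations from raw measurements (MTO is
#' graded from the scan columns alone, before AVS is examined), classify
#' PASO outcomes, build the hierarchical accuracy report, estimate
#' diagnostic rates, and run the AVS-failure bootstrap. Deterministic for
#' a fixed seed. With `out_dir` set, writes the cohort snapshot
#' (`cohort.csv`, including per-patient grades and outcomes) and a
#' machine-readable `summary.json`.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report`: `cohort`, `accuracy`
#'   (per-limb [accuracy_difference()] results), `rates`, `bootstrap`,
#'   `summary` (plain-list rendering of the numbers) and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  cohort <- if (!is.null(config$input)) {
    x <- read_cohort(config$input)
    x <- grade_cohort(x, config$grading)
    classify_cohort(x, config$paso)
  } else {
    cfg <- config$cohort
    cfg$seed <- config$seed
    generate_cohort(cfg, config$grading, config$paso)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  accuracy <- stage("paired_accuracy",
                    hierarchical_report(cohort, config$level, config$margin))
  rates <- stage("diagnostic_rates",
                 diagnostic_rates(cohort, "h1", config$level))
  boot <- stage("bootstrap",
                bootstrap_avs_failure_sensitivity(
                  cohort, "h1", n_reps = config$bootstrap_reps,
                  seed = config$seed + 1L, level = config$level))
  summary <- list(
    n_patients = nrow(cohort),
    n_surgery = sum(cohort$management == "surgery"),
    n_medical = sum(cohort$management == "medical"),
    n_deferred = sum(cohort$management == "deferred"),
    accuracy = lapply(accuracy, function(a) list(
      endpoint = a$table$endpoint, n = a$table$n,
      n_both = a$table$n_both, n_mto_only = a$table$n_mto_only,
      n_avs_only = a$table$n_avs_only, n_neither = a$table$n_neither,
      accuracy_mto = a$accuracy_mto, accuracy_avs = a$accuracy_avs,
      difference = a$estimate,
      ci_lower = a$interval$lower, ci_upper = a$interval$upper,
      p_superiority = a$p_superiority,
      p_noninferiority = a$p_noninferiority)),
    rates = lapply(rates[c("mto", "avs")], function(t) list(
      sensitivity = t$sensitivity$estimate,
      sensitivity_ci = c(t$sensitivity$interval$lower,
                         t$sensitivity$interval$upper),
      false_positive_rate = t$false_positive_rate$estimate,
      false_positive_ci = c(t$false_positive_rate$interval$lower,
                            t$false_positive_rate$interval$upper))),
    bootstrap = list(ci = c(boot$interval$lower, boot$interval$upper),
                     sensitive = boot$sensitive,
                     degenerate = boot$degenerate,
                     n_reps = boot$n_reps),
    seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cohort = cohort, accuracy = accuracy, rates = rates,
                 bootstrap = boot, summary = summary, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d patients (%d surgery / %d medical / %d deferred)\n",
              x$summary$n_patients, x$summary$n_surgery, x$summary$n_medical,
              x$summary$n_deferred))
  for (a in x$accuracy) print(a)
  print(x$rates)
  print(x$bootstrap)
  invisible(x)
}
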