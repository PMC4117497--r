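#' Default end-to-end pipeline configuration
#'
#' The configuration schema has six blocks:
#' \describe{
#'   \item{stages}{List of four stage maps with keys `name`, `ideal_time`,
#'     `mean_duration`, `exceed_frac`, `improvement_estimate`,
#'     `improvement_interval` (two fractions, low then high).}
#'   \item{outcomes}{Named map outcome -> Boolean recipe string.}
#'   \item{cohort}{`n` (patients), `seed`, `noise_rate`. The default `n` of
#'     3000 is chosen so that every one of the 16 condition configurations
#'     is observed with high probability, making the downstream QCA stage
#'     exact; pass `n = 29` for a study-sized cohort.}
#'   \item{qca}{`outcomes` to analyse, `solution` type
#'     (complex/parsimonious/intermediate), `inclusion_cutoff`, optional
#'     `expectations` map.}
#'   \item{sd}{`dt`, `horizon`, `arrivals` (mode/value).}
#'   \item{sensitivity}{`n_runs`, `seed`.}
#' }
#'
#' @return A configuration list that [validate_pipeline_config()] accepts.
#' @export
default_pipeline_config <- function() {
  specs <- default_stage_specs()
  list(
    stages = purrr::pmap(specs, function(stage, ideal_time, mean_duration,
                                         exceed_frac, improvement_estimate,
                                         improvement_low, improvement_high) {
      list(
        name = stage, ideal_time = ideal_time, mean_duration = mean_duration,
        exceed_frac = exceed_frac, improvement_estimate = improvement_estimate,
        improvement_interval = c(improvement_low, improvement_high)
      )
    }),
    outcomes = default_outcome_recipes(),
    cohort = list(n = 3000, seed = 101, noise_rate = 0),
    qca = list(outcomes = c("EF", "LOS"), solution = "intermediate",
               inclusion_cutoff = 1.0, expectations = NULL),
    sd = list(dt = 0.5, horizon = 600,
              arrivals = list(mode = "pulse", value = 29)),
    sensitivity = list(n_runs = 2000, seed = 101)
  )
}

#' Validate a pipeline configuration
#'
#' Checks the full schema documented in [default_pipeline_config()]; every
#' problem is reported with the offending key, and nothing is executed on an
#' invalid configuration.
#'
#' @param config Configuration list.
#' @return `config`, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  fail <- function(msg) rlang::abort(paste0("invalid config: ", msg))
  for (block in c("stages", "outcomes", "cohort", "qca", "sd", "sensitivity")) {
    if (is.null(config[[block]])) fail(paste0("missing block '", block, "'"))
  }
  if (length(config$stages) != 4) fail("stages must list the four care stages")
  for (st in config$stages) {
    for (key in c("name", "ideal_time", "mean_duration", "exceed_frac",
                  "improvement_estimate", "improvement_interval")) {
      if (is.null(st[[key]])) {
        fail(paste0("stage block missing key '", key, "'"))
      }
    }
  }
  specs <- config_stage_specs(config)   # runs validate_stage_specs()
  recipes <- config$outcomes
  if (is.null(names(recipes)) || any(!nzchar(names(recipes)))) {
    fail("outcomes must be a named map of recipe strings")
  }
  purrr::walk(recipes, parse_qca_expression, conditions = specs$stage)
  n <- config$cohort$n
  if (is.null(n) || !is.numeric(n) || n < 1 || n != floor(n)) {
    fail("cohort$n must be an integer >= 1")
  }
  nr <- config$cohort$noise_rate %||% 0
  if (!is.numeric(nr) || nr < 0 || nr > 1) fail("cohort$noise_rate must lie in [0, 1]")
  unknown <- setdiff(config$qca$outcomes, names(recipes))
  if (length(unknown) > 0) {
    fail(paste0("qca$outcomes references unknown outcome(s): ",
                paste(unknown, collapse = ", ")))
  }
  if (!config$qca$solution %in% c("complex", "parsimonious", "intermediate")) {
    fail("qca$solution must be complex, parsimonious or intermediate")
  }
  cut <- config$qca$inclusion_cutoff %||% 1
  if (!is.numeric(cut) || cut <= 0.5 || cut > 1) {
    fail("qca$inclusion_cutoff must lie in (0.5, 1]")
  }
  # build_stemi_model validates dt/horizon/arrivals
  build_stemi_model(specs, arrivals = config$sd$arrivals,
                    dt = config$sd$dt, horizon = config$sd$horizon)
  runs <- config$sensitivity$n_runs
  if (is.null(runs) || !is.numeric(runs) || runs < 2) {
    fail("sensitivity$n_runs must be an integer >= 2")
  }
  invisible(config)
}

# Stage-spec tibble from the config's stage blocks.
config_stage_specs <- function(config) {
  specs <- purrr::map_dfr(config$stages, function(st) {
    tibble::tibble(
      stage = st$name,
      ideal_time = st$ideal_time,
      mean_duration = st$mean_duration,
      exceed_frac = st$exceed_frac,
      improvement_estimate = st$improvement_estimate,
      improvement_low = st$improvement_interval[[1]],
      improvement_high = st$improvement_interval[[2]]
    )
  })
  validate_stage_specs(specs)
  specs
}

#' Run the full delay-analysis pipeline
#'
#' Executes the whole analysis chain from one configuration: generate the
#' synthetic cohort, summarise per-stage delays, run csQCA for each
#' configured outcome, simulate the baseline and improvement-policy
#' pathway, and run the Monte-Carlo sensitivity analysis. The run is
#' deterministic given the seeds in the configuration, and the returned
#' report carries a provenance block (config hash, seeds, package version)
#' sufficient to reproduce it.
#'
#' @param config Configuration list, see [default_pipeline_config()];
#'   validated before anything executes.
#' @param out_dir Optional directory; when given, the cohort, truth tables,
#'   trajectories, bands and the JSON report are written there.
#' @return An `analysis_report` list with elements `provenance`,
#'   `cohort_summary`, `qca`, `sd` and `sensitivity`.
#' @examples
#' \donttest{
#' report <- run_pipeline()
#' report$qca$EF$expression
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  validate_pipeline_config(config)
  specs <- config_stage_specs(config)

  cohort <- generate_cohort(
    stage_specs = specs, outcome_recipes = config$outcomes,
    n = config$cohort$n, seed = config$cohort$seed,
    noise_rate = config$cohort$noise_rate %||% 0
  )
  summary <- summarize_cohort(cohort, specs)

  qca_results <- purrr::map(
    stats::setNames(config$qca$outcomes, config$qca$outcomes),
    function(outcome) {
      m <- binarize_conditions(cohort, outcome = outcome,
                               conditions = specs$stage)
      tt <- build_truth_table(m, inclusion_cutoff = config$qca$inclusion_cutoff %||% 1)
      sol <- switch(config$qca$solution,
        complex = minimize_truth_table(tt, use_remainders = FALSE),
        parsimonious = minimize_truth_table(tt, use_remainders = TRUE),
        intermediate = intermediate_solution(tt, config$qca$expectations)
      )
      list(truth_table = tt, solution = sol)
    }
  )

  model <- build_stemi_model(specs, arrivals = config$sd$arrivals,
                             dt = config$sd$dt, horizon = config$sd$horizon)
  policy <- specs$improvement_estimate
  comparison <- compare_scenarios(
    model, list(baseline = rep(0, 4), policy = policy), simulate = TRUE
  )
  bands <- run_sensitivity(model, n_runs = config$sensitivity$n_runs,
                           seed = config$sensitivity$seed)

  report <- structure(
    list(
      provenance = list(
        package = "stemipathway",
        version = as.character(utils::packageVersion("stemipathway")),
        config_hash = rlang::hash(config),
        cohort_seed = config$cohort$seed,
        sensitivity_seed = config$sensitivity$seed
      ),
      cohort_summary = list(
        stages = summary$stages,
        total_mean = summary$total_mean,
        n = summary$n
      ),
      qca = purrr::map(qca_results, function(res) {
        g <- glance.qca_solution(res$solution)
        list(
          type = g$type, expression = g$expression,
          n_implicants = g$n_implicants,
          consistency = g$consistency, coverage = g$coverage,
          implicants = res$solution$details
        )
      }),
      sd = list(
        stage_table = comparison$stages,
        totals = comparison$totals
      ),
      sensitivity = list(
        n_runs = attr(bands, "n_runs"),
        n_excluded = attr(bands, "n_excluded"),
        final_p95 = c(lo = bands$p95_lo[nrow(bands)],
                      hi = bands$p95_hi[nrow(bands)])
      )
    ),
    class = "analysis_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    purrr::iwalk(qca_results, function(res, outcome) {
      write_truth_table_csv(res$truth_table,
                            file.path(out_dir, paste0("truth_table_", outcome, ".csv")))
    })
    purrr::iwalk(comparison$trajectories, function(traj, name) {
      write_trajectory_csv(traj,
                           file.path(out_dir, paste0("trajectory_", name, ".csv")))
    })
    write_bands_csv(bands, file.path(out_dir, "sensitivity_bands.csv"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("STEMI care-pathway analysis report\n")
  cat("  cohort: ", x$cohort_summary$n, " patients, mean total time ",
      round(x$cohort_summary$total_mean, 1), " min\n", sep = "")
  for (outcome in names(x$qca)) {
    cat("  QCA [", outcome, "]: ", x$qca[[outcome]]$expression, "\n", sep = "")
  }
  cat("  steady-state total time:",
      paste(x$sd$totals$scenario, round(x$sd$totals$total_time, 1),
            sep = "=", collapse = ", "), "min\n")
  cat("  sensitivity: ", x$sensitivity$n_runs, " runs\n", sep = "")
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' The report contains no timestamps, so two runs from the same
#' configuration produce byte-identical files.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
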