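#' Monte-Carlo sensitivity analysis of improvement policies
#'
#' Repeatedly simulates the pathway with per-stage improvement fractions
#' drawn independently and uniformly from their uncertainty intervals, and
#' summarises the percent-retained series with central percentile envelopes
#' at 50, 75, 95 and 100 per cent coverage (the 100 per cent envelope is the
#' pointwise min/max of all runs). Envelopes are nested by construction.
#'
#' @param model A `stemi_sd_model`.
#' @param intervals Data frame with columns `stage`, `low`, `high` giving
#'   the per-stage improvement bounds (`0 <= low <= high < 1`); defaults to
#'   the `improvement_low`/`improvement_high` columns of the model's stage
#'   table.
#' @param n_runs Number of Monte-Carlo runs (default 20000).
#' @param seed Integer seed; the whole band object is deterministic given
#'   the seed.
#' @param keep_runs Keep the full run-by-time percent-retained matrix as an
#'   attribute (memory-heavy for large `n_runs`)?
#' @return A `sensitivity_bands` tibble with columns `t`, `p50_lo`,
#'   `p50_hi`, `p75_lo`, `p75_hi`, `p95_lo`, `p95_hi`, `min`, `max`.
#'   Attributes record `n_runs`, `n_excluded`, `seed` and the sampled
#'   improvement draws.
#' @examples
#' model <- build_stemi_model(arrivals = list(mode = "pulse", value = 29),
#'                            dt = 0.5, horizon = 300)
#' bands <- run_sensitivity(model, n_runs = 200, seed = 1)
#' head(bands)
#' @export
run_sensitivity <- function(model, intervals = NULL, n_runs = 20000,
                            seed = NULL, keep_runs = FALSE) {
  stopifnot(inherits(model, "stemi_sd_model"))
  if (!is.numeric(n_runs) || n_runs < 2 || n_runs != floor(n_runs)) {
    rlang::abort("n_runs must be an integer >= 2")
  }
  if (is.null(intervals)) {
    intervals <- tibble::tibble(
      stage = model$stage_specs$stage,
      low = model$stage_specs$improvement_low,
      high = model$stage_specs$improvement_high
    )
  }
  if (!all(c("stage", "low", "high") %in% names(intervals)) ||
      !identical(intervals$stage, names(model$tau))) {
    rlang::abort("intervals must have columns stage, low, high for the four stages in order")
  }
  if (any(intervals$low < 0) || any(intervals$low > intervals$high) ||
      any(intervals$high >= 1)) {
    rlang::abort("improvement intervals must satisfy 0 <= low <= high < 1")
  }
  draw_and_run <- function() {
    u <- vapply(seq_len(4), function(s) {
      stats::runif(n_runs, intervals$low[s], intervals$high[s])
    }, numeric(n_runs))
    if (n_runs == 1) u <- matrix(u, 1)
    tau_eff <- sweep(1 - u, 2, model$tau, "*")
    # runs violating the integration stability guard are excluded, not run
    ok <- apply(tau_eff, 1, min) >= 5 * model$dt
    if (!all(ok)) {
      rlang::warn(paste0(
        sum(!ok), " run(s) excluded: effective residence time below the ",
        "dt stability guard"
      ))
    }
    res <- integrate_chain(tau_eff[ok, , drop = FALSE], model$arrivals,
                           model$dt, model$horizon,
                           tau_start = model$tau,
                           adjustment_time = model$adjustment_time)
    list(u = u, ok = ok, times = res$times, pct = res$percent_retained)
  }
  res <- if (is.null(seed)) draw_and_run() else with_preserved_seed(seed, draw_and_run())

  env <- function(p_cov) {
    a <- (1 - p_cov) / 2
    lo <- apply(res$pct, 2, stats::quantile, probs = a, na.rm = TRUE, names = FALSE)
    hi <- apply(res$pct, 2, stats::quantile, probs = 1 - a, na.rm = TRUE, names = FALSE)
    list(lo = lo, hi = hi)
  }
  e50 <- env(0.50); e75 <- env(0.75); e95 <- env(0.95)
  bands <- tibble::tibble(
    t = res$times,
    p50_lo = e50$lo, p50_hi = e50$hi,
    p75_lo = e75$lo, p75_hi = e75$hi,
    p95_lo = e95$lo, p95_hi = e95$hi,
    min = suppressWarnings(apply(res$pct, 2, min, na.rm = TRUE)),
    max = suppressWarnings(apply(res$pct, 2, max, na.rm = TRUE))
  )
  bands$min[!is.finite(bands$min)] <- NA_real_
  bands$max[!is.finite(bands$max)] <- NA_real_
  structure(bands,
            n_runs = sum(res$ok), n_excluded = sum(!res$ok), seed = seed,
            draws = res$u[res$ok, , drop = FALSE],
            runs = if (keep_runs) res$pct else NULL,
            class = c("sensitivity_bands", class(tibble::tibble())))
}

#' @export
print.sensitivity_bands <- function(x, ...) {
  cat("Sensitivity bands over ", attr(x, "n_runs"), " runs",
      if (attr(x, "n_excluded") > 0) paste0(" (", attr(x, "n_excluded"), " excluded)"),
      "\n", sep = "")
  NextMethod()
  invisible(x)
}

#' @rdname run_sensitivity
#' @param x A `sensitivity_bands` object.
#' @param ... Unused.
#' @method tidy sensitivity_bands
#' @export
tidy.sensitivity_bands <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::rename(p100_lo = "min", p100_hi = "max") |>
    tidyr::pivot_longer(-"t",
                        names_to = c("band", ".value"),
                        names_pattern = "p(\\d+)_(lo|hi)") |>
    dplyr::mutate(band = paste0(.data$band, "%"))
}

#' @describeIn run_sensitivity Ribbon plot of the nested percentile
#'   envelopes.
#' @param object A `sensitivity_bands` object.
#' @method autoplot sensitivity_bands
#' @export
autoplot.sensitivity_bands <- function(object, ...) {
  df <- tidy.sensitivity_bands(object) |>
    dplyr::mutate(band = factor(.data$band, levels = c("100%", "95%", "75%", "50%")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$band)
    ) +
    ggplot2::scale_fill_manual(
      values = c(`100%` = "#bdbdbd", `95%` = "#6baed6",
                 `75%` = "#74c476", `50%` = "#fee08b")
    ) +
    ggplot2::labs(x = "Time (min)", y = "Percent retained (%)",
                  fill = "Coverage",
                  title = "Monte-Carlo sensitivity of total retention")
}

#' Uniform improvement fraction required to hit a target total time
#'
#' Solves `sum(tau_s * (1 - u)) = target_total` for the single improvement
#' fraction applied to every stage: `u = 1 - target_total / sum(tau_s)`.
#' The result is verified by one simulation of the policy.
#'
#' @param model A `stemi_sd_model`.
#' @param target_total Target mean door-in-door-out time in minutes,
#'   strictly between 0 and the baseline total `sum(tau_s)`.
#' @return The uniform improvement fraction, with the simulated total time
#'   attached as attribute `achieved_total`.
#' @examples
#' find_required_improvement(build_stemi_model(), 30)  # ~0.841
#' @export
find_required_improvement <- function(model, target_total) {
  stopifnot(inherits(model, "stemi_sd_model"))
  total0 <- sum(model$tau)
  if (!is.numeric(target_total) || length(target_total) != 1 ||
      target_total <= 0 || target_total > total0) {
    rlang::abort(paste0("target_total must lie in (0, ", total0, "] minutes"))
  }
  u <- 1 - target_total / total0
  tau_eff <- model$tau * (1 - u)
  # verify by simulation at a step respecting the policy's stability guard
  dt <- min(min(tau_eff) / 10, model$dt)
  horizon <- 10 * max(tau_eff)
  check <- build_stemi_model(model$stage_specs,
                             arrivals = list(mode = "rate", value = 1),
                             dt = dt, horizon = horizon)
  traj <- simulate_pathway(check, improvements = rep(u, 4))
  achieved <- sum(traj[nrow(traj), c("S_FMC", "S_ECG", "S_TXF", "S_TWT")])
  if (abs(achieved - target_total) > 0.02 * target_total) {
    rlang::abort("simulation check failed to confirm the required improvement")
  }
  structure(u, achieved_total = as.numeric(achieved))
}

#' Compare improvement scenarios on the same pathway model
#'
#' Tabulates per-stage effective residence times for each scenario and the
#' retained-time reduction relative to the first (reference) scenario,
#' together with the analytic total times.
#'
#' @param model A `stemi_sd_model`.
#' @param scenarios Named list of at least two improvement vectors (length
#'   four each); the first entry is the reference.
#' @param simulate Also attach full trajectories (one per scenario) as
#'   attribute `trajectories`?
#' @return A `scenario_comparison`; `tidy()` gives the per-stage table,
#'   `glance()` the per-scenario totals.
#' @examples
#' model <- build_stemi_model()
#' compare_scenarios(model, list(baseline = c(0, 0, 0, 0),
#'                               policy = c(0.4, 0.4, 0.5, 0.5)))
#' @export
compare_scenarios <- function(model, scenarios, simulate = FALSE) {
  stopifnot(inherits(model, "stemi_sd_model"))
  if (!is.list(scenarios) || length(scenarios) < 2) {
    rlang::abort("scenarios must be a named list of at least two improvement vectors")
  }
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  purrr::walk(scenarios, validate_improvements)
  ref <- model$tau * (1 - scenarios[[1]])
  stages <- purrr::imap_dfr(scenarios, function(u, name) {
    tau_eff <- model$tau * (1 - u)
    tibble::tibble(
      scenario = name,
      stage = names(model$tau),
      improvement = unname(u),
      tau_effective = unname(tau_eff),
      reduction = unname(ref - tau_eff)
    )
  })
  totals <- purrr::imap_dfr(scenarios, function(u, name) {
    tibble::tibble(
      scenario = name,
      total_time = steady_state_total_time(model, u),
      total_reduction = steady_state_total_time(model, scenarios[[1]]) -
        steady_state_total_time(model, u)
    )
  })
  trajectories <- if (simulate) {
    purrr::map(scenarios, function(u) simulate_pathway(model, u))
  } else NULL
  structure(
    list(stages = stages, totals = totals, trajectories = trajectories),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (reference: ", x$totals$scenario[1], ")\n", sep = "")
  print(x$stages)
  print(x$totals)
  invisible(x)
}

#' @rdname compare_scenarios
#' @param x A `scenario_comparison`.
#' @param ... Unused.
#' @method tidy scenario_comparison
#' @export
tidy.scenario_comparison <- function(x, ...) x$stages

#' @rdname compare_scenarios
#' @method glance scenario_comparison
#' @export
glance.scenario_comparison <- function(x, ...) x$totals
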