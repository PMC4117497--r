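#' Build the four-stage stock-and-flow model of the care pathway
#'
#' The pathway is modelled as an aging chain: Arrivals flow into the FMC
#' stock, then through the ECG, TXF and TWT stocks, and finally out as
#' transfers to the PCI center. Each stage `s` drains as a first-order
#' outflow `stock_s / tau_s`, where the baseline residence time `tau_s` is
#' the stage's mean duration. Improvement policies act as balancing loops
#' whose settled effect shortens the residence time to
#' `tau_s * (1 - u_s)`; an optional goal-seeking mode lets the residence
#' time relax toward that target with a configurable adjustment time
#' instead of applying it instantly.
#'
#' @param stage_specs Stage table, see [default_stage_specs()]; the four
#'   stages must appear in pathway order FMC, ECG, TXF, TWT.
#' @param arrivals List with `mode` either `"rate"` (constant arrivals of
#'   `value` patients per minute) or `"pulse"` (`value` patients arriving at
#'   time zero).
#' @param dt Integration step in minutes; must satisfy
#'   `dt <= min(tau) / 5`, the stability guard for the explicit Euler
#'   integrator.
#' @param horizon Simulation horizon in minutes.
#' @param adjustment_time Optional balancing-loop adjustment time in
#'   minutes; `NULL` (default) applies policies as settled residence-time
#'   reductions.
#' @return A `stemi_sd_model` object.
#' @examples
#' model <- build_stemi_model()
#' steady_state_total_time(model)
#' @export
build_stemi_model <- function(stage_specs = default_stage_specs(),
                              arrivals = list(mode = "rate", value = 1),
                              dt = 0.5, horizon = 1000,
                              adjustment_time = NULL) {
  if (is.null(stage_specs) || nrow(stage_specs) == 0) {
    rlang::abort("stage_specs must contain the four pathway stages")
  }
  validate_stage_specs(stage_specs)
  tau <- stats::setNames(stage_specs$mean_duration, stage_specs$stage)
  if (!is.list(arrivals) || !arrivals$mode %in% c("rate", "pulse") ||
      !is.numeric(arrivals$value) || arrivals$value <= 0) {
    rlang::abort("arrivals must be list(mode = 'rate'|'pulse', value > 0)")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    rlang::abort("dt must be a positive number of minutes")
  }
  if (dt > min(tau) / 5) {
    rlang::abort(paste0(
      "dt = ", dt, " exceeds the stability guard min(tau)/5 = ",
      signif(min(tau) / 5, 4), " min"
    ))
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < dt) {
    rlang::abort("horizon must be at least one integration step")
  }
  if (!is.null(adjustment_time) &&
      (!is.numeric(adjustment_time) || adjustment_time <= 0)) {
    rlang::abort("adjustment_time must be NULL or a positive number of minutes")
  }
  structure(
    list(
      stage_specs = stage_specs,
      tau = tau,
      arrivals = arrivals,
      dt = dt,
      horizon = horizon,
      adjustment_time = adjustment_time
    ),
    class = "stemi_sd_model"
  )
}

#' @export
print.stemi_sd_model <- function(x, ...) {
  cat("STEMI care-pathway aging chain\n")
  cat("  residence times (min):",
      paste(names(x$tau), round(x$tau, 1), sep = "=", collapse = ", "), "\n")
  cat("  arrivals:", x$arrivals$mode, "=", x$arrivals$value,
      "| dt =", x$dt, "min | horizon =", x$horizon, "min\n")
  invisible(x)
}

validate_improvements <- function(improvements, n_stages = 4) {
  if (!is.numeric(improvements) || length(improvements) != n_stages) {
    rlang::abort(paste0("improvements must be a numeric vector of length ",
                        n_stages))
  }
  if (any(improvements < 0) || any(improvements >= 1)) {
    rlang::abort("each improvement fraction must satisfy 0 <= u < 1")
  }
  improvements
}

# Vectorised explicit-Euler integrator for the four-stage chain.
# tau_eff: n_runs x 4 matrix of settled residence times. Returns the
# percent-retained matrix (n_runs x n_times) plus, for n_runs == 1, the
# full state history used to assemble a trajectory tibble.
integrate_chain <- function(tau_eff, arrivals, dt, horizon,
                            tau_start = NULL, adjustment_time = NULL,
                            keep_states = FALSE) {
  n_runs <- nrow(tau_eff)
  n_steps <- round(horizon / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  S <- matrix(0, n_runs, 4)
  transferred <- numeric(n_runs)
  if (arrivals$mode == "pulse") {
    S[, 1] <- arrivals$value
    cum_arr <- rep(arrivals$value, n_runs)
    rate <- 0
  } else {
    cum_arr <- numeric(n_runs)
    rate <- arrivals$value
  }
  tau <- if (is.null(adjustment_time)) tau_eff else {
    if (is.null(tau_start)) rlang::abort("tau_start required for goal seeking")
    matrix(rep(tau_start, each = n_runs), n_runs, 4)
  }
  pct <- matrix(NA_real_, n_runs, n_steps + 1)
  pct[, 1] <- ifelse(cum_arr > 0, 100 * rowSums(S) / cum_arr, NA_real_)
  states <- if (keep_states) {
    list(S = array(0, c(n_steps + 1, 4)), out = array(0, c(n_steps + 1, 4)),
         transferred = numeric(n_steps + 1), cum_arr = numeric(n_steps + 1))
  } else NULL
  if (keep_states) {
    states$S[1, ] <- S[1, ]
    states$out[1, ] <- S[1, ] / tau[1, ]
    states$transferred[1] <- transferred[1]
    states$cum_arr[1] <- cum_arr[1]
  }
  for (step in seq_len(n_steps)) {
    outflow <- S / tau
    S[, 1] <- S[, 1] + dt * (rate - outflow[, 1])
    S[, 2] <- S[, 2] + dt * (outflow[, 1] - outflow[, 2])
    S[, 3] <- S[, 3] + dt * (outflow[, 2] - outflow[, 3])
    S[, 4] <- S[, 4] + dt * (outflow[, 3] - outflow[, 4])
    transferred <- transferred + dt * outflow[, 4]
    cum_arr <- cum_arr + dt * rate
    if (!is.null(adjustment_time)) {
      tau <- tau + dt * (tau_eff - tau) / adjustment_time
    }
    if (anyNA(S) || any(!is.finite(S))) {
      rlang::abort(paste0(
        "integration diverged at t = ", signif(times[step + 1], 5),
        " min (non-finite stock); reduce dt"
      ))
    }
    pct[, step + 1] <- ifelse(cum_arr > 0, 100 * rowSums(S) / cum_arr, NA_real_)
    if (keep_states) {
      states$S[step + 1, ] <- S[1, ]
      states$out[step + 1, ] <- (S / tau)[1, ]
      states$transferred[step + 1] <- transferred[1]
      states$cum_arr[step + 1] <- cum_arr[1]
    }
  }
  list(times = times, percent_retained = pct, states = states)
}

#' Simulate the care-pathway model under an improvement policy
#'
#' Integrates the aging chain with explicit fixed-step Euler and returns the
#' full trajectory: stocks, flows, cumulative arrivals and transfers, and
#' the percent of arrived patients still retained in the pathway.
#'
#' @param model A `stemi_sd_model` from [build_stemi_model()].
#' @param improvements Numeric vector of four improvement fractions
#'   `u` in \[0, 1), one per stage in pathway order; residence times become
#'   `tau * (1 - u)`.
#' @return An `sd_trajectory` tibble with columns `t`, `S_FMC`, `S_ECG`,
#'   `S_TXF`, `S_TWT`, `outflow_*`, `arrivals_cum`, `transferred`,
#'   `percent_retained`.
#' @examples
#' model <- build_stemi_model(horizon = 300)
#' traj <- simulate_pathway(model, improvements = c(0.4, 0.4, 0.5, 0.5))
#' tail(traj)
#' @export
simulate_pathway <- function(model, improvements = c(0, 0, 0, 0)) {
  stopifnot(inherits(model, "stemi_sd_model"))
  validate_improvements(improvements)
  tau_eff <- model$tau * (1 - improvements)
  if (is.null(model$adjustment_time) && model$dt > min(tau_eff) / 5) {
    rlang::abort(paste0(
      "dt = ", model$dt, " exceeds min(effective tau)/5 = ",
      signif(min(tau_eff) / 5, 4),
      " min under this policy; rebuild the model with a smaller dt"
    ))
  }
  res <- integrate_chain(
    matrix(tau_eff, 1), model$arrivals, model$dt, model$horizon,
    tau_start = model$tau, adjustment_time = model$adjustment_time,
    keep_states = TRUE
  )
  st <- res$states
  traj <- tibble::tibble(
    t = res$times,
    S_FMC = st$S[, 1], S_ECG = st$S[, 2], S_TXF = st$S[, 3], S_TWT = st$S[, 4],
    outflow_FMC = st$out[, 1], outflow_ECG = st$out[, 2],
    outflow_TXF = st$out[, 3], outflow_TWT = st$out[, 4],
    arrivals_cum = st$cum_arr,
    transferred = st$transferred,
    percent_retained = res$percent_retained[1, ]
  )
  structure(traj,
            model = model, improvements = improvements,
            class = c("sd_trajectory", class(tibble::tibble())))
}

#' Percent of arrived patients retained in the pathway at time t
#'
#' `100 * (sum of stocks at t) / (cumulative arrivals at t)`, linearly
#' interpolated on the trajectory grid.
#'
#' @param trajectory An `sd_trajectory` from [simulate_pathway()].
#' @param t Time in minutes, within the simulated horizon and not before
#'   the first arrival.
#' @return Percentage in \[0, 100\].
#' @export
percent_retained <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "sd_trajectory"))
  if (!is.numeric(t) || length(t) != 1) rlang::abort("t must be a single time")
  if (t < min(trajectory$t) || t > max(trajectory$t)) {
    rlang::abort("t outside the simulated horizon")
  }
  ok <- !is.na(trajectory$percent_retained)
  if (!any(ok) || t < min(trajectory$t[ok])) {
    rlang::abort("percent retained undefined before the first arrival")
  }
  stats::approx(trajectory$t[ok], trajectory$percent_retained[ok], xout = t)$y
}

#' Analytic steady-state mean door-in-door-out time
#'
#' Under constant arrivals the chain settles to stocks
#' `S_s = lambda * tau_s * (1 - u_s)`; by Little's law the mean total time
#' in the pathway is the sum of effective residence times,
#' `sum(tau_s * (1 - u_s))`, independent of the arrival rate. This is the
#' analytic companion the simulator is checked against.
#'
#' @inheritParams simulate_pathway
#' @return Minutes.
#' @examples
#' steady_state_total_time(build_stemi_model())                 # 189
#' steady_state_total_time(build_stemi_model(), c(0.4, 0.4, 0.5, 0.5))  # 98
#' @export
steady_state_total_time <- function(model, improvements = c(0, 0, 0, 0)) {
  stopifnot(inherits(model, "stemi_sd_model"))
  validate_improvements(improvements)
  sum(model$tau * (1 - improvements))
}

#' @describeIn simulate_pathway Plot stocks and percent retained over time.
#' @param object An `sd_trajectory`.
#' @param ... Unused.
#' @method autoplot sd_trajectory
#' @export
autoplot.sd_trajectory <- function(object, ...) {
  df <- object |>
    tibble::as_tibble() |>
    dplyr::select("t", dplyr::starts_with("S_")) |>
    tidyr::pivot_longer(-"t", names_to = "stock", values_to = "patients") |>
    dplyr::mutate(stock = factor(sub("^S_", "", .data$stock),
                                 levels = stemi_stages))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$patients,
                                   colour = .data$stock)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Patients in stage",
                  colour = "Stage",
                  title = "Care-pathway stocks over time")
}
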