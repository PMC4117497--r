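test_that("model construction validates stages, arrivals and the dt guard", {
  model <- build_stemi_model()
  expect_equal(unname(model$tau), c(7, 28, 76, 78))
  expect_error(build_stemi_model(dt = 2), "stability guard")
  expect_error(build_stemi_model(stage_specs = default_stage_specs()[0, ]),
               "four")
  expect_error(build_stemi_model(arrivals = list(mode = "drip", value = 1)),
               "arrivals")
  expect_error(build_stemi_model(horizon = 0.1), "horizon")
  # policies shortening residence times can break the guard post hoc
  tight <- build_stemi_model(dt = 1.2)
  expect_error(simulate_pathway(tight, improvements = c(0.9, 0, 0, 0)),
               "stability|effective")
})

test_that("steady-state total time is the sum of effective residence times", {
  model <- build_stemi_model()
  expect_equal(steady_state_total_time(model), 189)
  expect_equal(steady_state_total_time(model, c(0.4, 0.4, 0.5, 0.5)), 98)
  expect_equal(steady_state_total_time(model, rep(1 - 30 / 189, 4)), 30)
  expect_error(steady_state_total_time(model, c(0.5, 0.5, 0.5, 1)), "u < 1")
})

test_that("constant-arrival simulation conserves mass and obeys Little's law", {
  model <- build_stemi_model(dt = 0.5, horizon = 1200)
  for (u in list(c(0, 0, 0, 0), c(0.4, 0.4, 0.5, 0.5))) {
    traj <- simulate_pathway(model, improvements = u)
    stocks <- traj$S_FMC + traj$S_ECG + traj$S_TXF + traj$S_TWT
    # arrivals = in-system + transferred at every step
    err <- abs(traj$arrivals_cum - (stocks + traj$transferred))
    expect_lt(max(err / pmax(traj$arrivals_cum, 1)), 1e-6)
    expect_true(all(stocks >= 0))
    # lambda = 1/min, so total work in progress -> mean total time
    expect_equal(stocks[length(stocks)], steady_state_total_time(model, u),
                 tolerance = 1e-3)
    # per-stage steady state lambda * tau_eff
    tau_eff <- model$tau * (1 - u)
    expect_equal(unlist(traj[nrow(traj), c("S_FMC", "S_ECG", "S_TXF", "S_TWT")],
                        use.names = FALSE),
                 unname(tau_eff), tolerance = 1e-3)
  }
})

test_that("improvement policies monotonically reduce retention", {
  model <- build_stemi_model(arrivals = list(mode = "pulse", value = 29),
                             dt = 0.5, horizon = 400)
  base <- simulate_pathway(model)
  better <- simulate_pathway(model, improvements = c(0.2, 0.2, 0.2, 0.2))
  best <- simulate_pathway(model, improvements = c(0.5, 0.5, 0.6, 0.6))
  expect_true(all(better$percent_retained <= base$percent_retained + 1e-9))
  expect_true(all(best$percent_retained <= better$percent_retained + 1e-9))
  expect_lt(steady_state_total_time(model, c(0.5, 0.5, 0.6, 0.6)),
            steady_state_total_time(model, c(0.2, 0.2, 0.2, 0.2)))
})

test_that("percent retained starts at 100 for a pulse and drains to zero", {
  model <- build_stemi_model(arrivals = list(mode = "pulse", value = 29),
                             dt = 0.5, horizon = 2000)
  traj <- simulate_pathway(model)
  expect_equal(percent_retained(traj, 0), 100)
  expect_lt(percent_retained(traj, 2000), 0.5)
  expect_true(all(traj$percent_retained >= 0 &
                    traj$percent_retained <= 100 + 1e-9))
  expect_error(percent_retained(traj, 3000), "horizon")

  # before any arrival the ratio is undefined (rate mode, t = 0)
  rate_traj <- simulate_pathway(build_stemi_model(dt = 0.5, horizon = 10))
  expect_error(percent_retained(rate_traj, 0), "first arrival")
})

test_that("the pulse response matches the hypoexponential survival oracle", {
  tau <- c(7, 28, 76, 78)
  dt <- 0.01 * min(tau)
  model <- build_stemi_model(arrivals = list(mode = "pulse", value = 1),
                             dt = dt, horizon = 800)
  traj <- simulate_pathway(model)
  oracle <- hypoexp_survival(traj$t, 1 / tau)
  sup <- max(abs(traj$percent_retained / 100 - oracle))
  expect_lt(sup, 0.005)
  # the transfer-completion curve is the complementary CDF check
  completed <- traj$transferred / traj$arrivals_cum
  expect_lt(max(abs(completed - (1 - oracle))), 0.005)
})

test_that("halving the integration step barely changes the outputs", {
  coarse <- simulate_pathway(build_stemi_model(
    arrivals = list(mode = "pulse", value = 29), dt = 0.7, horizon = 350))
  fine <- simulate_pathway(build_stemi_model(
    arrivals = list(mode = "pulse", value = 29), dt = 0.35, horizon = 350))
  shared <- fine$t %in% coarse$t
  expect_lt(max(abs(fine$percent_retained[shared] - coarse$percent_retained)),
            0.5)
})

test_that("goal-seeking mode relaxes residence times toward the policy target", {
  settled <- build_stemi_model(dt = 0.5, horizon = 2500)
  seeking <- build_stemi_model(dt = 0.5, horizon = 2500, adjustment_time = 30)
  u <- c(0.4, 0.4, 0.5, 0.5)
  s_traj <- simulate_pathway(settled, u)
  g_traj <- simulate_pathway(seeking, u)
  # same steady state once the balancing loops settle
  expect_equal(
    sum(g_traj[nrow(g_traj), c("S_FMC", "S_ECG", "S_TXF", "S_TWT")]),
    sum(s_traj[nrow(s_traj), c("S_FMC", "S_ECG", "S_TXF", "S_TWT")]),
    tolerance = 1e-2)
  # conservation still holds along the adjustment transient
  stocks <- g_traj$S_FMC + g_traj$S_ECG + g_traj$S_TXF + g_traj$S_TWT
  err <- abs(g_traj$arrivals_cum - (stocks + g_traj$transferred))
  expect_lt(max(err / pmax(g_traj$arrivals_cum, 1)), 1e-6)
})
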