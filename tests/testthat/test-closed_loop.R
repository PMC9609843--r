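test_that("open-loop run decays toward the reference and equilibrium is conserved", {
  plant <- ref_plant()
  cfg <- simulation_config(dt = 10, horizon = 200000)
  traj <- simulate_closed_loop(plant, NULL, cfg)
  dev <- abs(traj$glucose_mg_dl - 70)
  expect_equal(dev[1], 130)
  # bounded by the initial deviation up to a sub-0.1% transient excursion
  expect_true(all(dev <= 130 * 1.001))
  expect_lt(dev[length(dev)], 130 * 0.05)
  # starting on the reference, every zero-at-equilibrium controller stays put
  eq <- simulation_config(G0 = 70, dt = 0.1, horizon = 50)
  for (ctrl in list(NULL,
                    lqr_design(plant, reference_lqr_weights()$Q, 1),
                    reference_smc_params(plant = plant),
                    reference_pid_gains())) {
    tr <- simulate_closed_loop(plant, ctrl, eq)
    expect_equal(max(abs(tr$glucose_mg_dl - 70)), 0)
    expect_equal(max(abs(tr$control_u)), 0)
  }
})

test_that("settling time matches the analytic value on an exponential recovery", {
  dt <- 0.05
  traj <- exp_trajectory(tau = 10, dt = dt)
  expect_equal(settling_time(traj, G_ref = 70, band = 0.02),
               10 * log(50), tolerance = dt / (10 * log(50)))
  flat <- exp_trajectory(dev0 = 0)
  expect_equal(settling_time(flat, G_ref = 70, band = 0.02), 0)
  slow <- exp_trajectory(tau = 1e5, horizon = 10)
  expect_true(is.na(settling_time(slow, G_ref = 70, band = 0.02)))
})

test_that("overshoot is direction-aware and zero without a crossing", {
  base <- exp_trajectory()
  expect_equal(overshoot(base, G_ref = 70), 0)
  dip <- base
  dip$glucose_mg_dl[100] <- 57
  expect_equal(overshoot(dip, G_ref = 70), 10)
  rising <- data.frame(time_s = 0:10,
                       glucose_mg_dl = c(40, 50, 60, 70, 80, 83, 78, 72, 70, 70, 70))
  expect_equal(overshoot(rising, G_ref = 70, G0 = 40),
               100 * 13 / 30, tolerance = 1e-12)
})

test_that("chattering metrics count sinusoid crossings and vanish for constants", {
  dt <- 1e-3
  t <- seq(0, 5, by = dt)
  sine <- data.frame(time_s = t, glucose_mg_dl = 70,
                     control_u = sin(2 * pi * 10 * t))
  ch <- chattering_index(sine, window_fraction = 0.2)
  expect_equal(ch$rate, 20, tolerance = 0.02)
  expect_equal(ch$amplitude, 2, tolerance = 0.02)
  const <- data.frame(time_s = t, glucose_mg_dl = 70, control_u = 5)
  ch0 <- chattering_index(const)
  expect_equal(ch0$rate, 0)
  expect_equal(ch0$amplitude, 0)
  short <- data.frame(time_s = 1:20, glucose_mg_dl = 70, control_u = 0)
  expect_error(chattering_index(short, window_fraction = 0.2), "10 samples")
})

test_that("low-pass filter has unit DC gain, first-order step response and -20 dB/decade rolloff", {
  dt <- 1e-3
  n <- 5000
  stepr <- low_pass_filter(rep(1, n), dt, cutoff = 1, y0 = 0)
  expect_equal(stepr[n], 1, tolerance = 0.01)              # DC gain
  expect_equal(stepr[round(1 / dt)], 1 - exp(-1), tolerance = 0.01)
  t <- seq(0, 10, by = dt)
  hi <- low_pass_filter(sin(100 * t), dt, cutoff = 1, y0 = 0)
  tail_amp <- max(abs(hi[t > 5]))
  expect_lt(tail_amp, 1.1 / 100)
})

test_that("RK4 integration converges at fourth order on a smooth state-feedback run", {
  plant <- ref_plant()
  sol <- lqr_design(plant, reference_lqr_weights()$Q, 1)
  final_g <- function(dt) {
    tr <- simulate_closed_loop(plant, sol,
                               simulation_config(dt = dt, horizon = 8))
    tr$glucose_mg_dl[nrow(tr)]
  }
  g1 <- final_g(0.4); g2 <- final_g(0.2); g3 <- final_g(0.1)
  ratio <- (g1 - g2) / (g2 - g3)
  expect_equal(ratio, 16, tolerance = 0.25)
})

test_that("sliding-mode control absorbs a matched sinusoidal disturbance that visibly perturbs the PID loop", {
  plant <- ref_plant()
  # amplitude 8 < 0.9 * k2 = 8.1, the matched-rejection condition
  dist <- list(amplitude = 8, omega = 2 * pi / 300, phase = 0)
  cfg0 <- simulation_config(dt = 0.01, horizon = 200)
  cfgd <- simulation_config(dt = 0.01, horizon = 200, disturbance = dist)
  smc <- reference_smc_params(plant = plant)
  sse_clean <- steady_state_error(simulate_closed_loop(plant, smc, cfg0))
  tr_smc <- simulate_closed_loop(plant, smc, cfgd)
  sse_dist <- steady_state_error(tr_smc)
  expect_lt(sse_dist, sse_clean + 0.02 * 130 + 100 * 0.01)
  osc_smc <- diff(range(tr_smc$glucose_mg_dl[tr_smc$time_s > 160]))
  # the PID loop, with no state feedback, lets the disturbance through at
  # roughly the open-loop gain and oscillates visibly more than SMC
  tr_pid <- simulate_closed_loop(plant, reference_pid_gains(),
                                 simulation_config(dt = 0.01, horizon = 200,
                                                   disturbance = dist))
  osc_pid <- diff(range(tr_pid$glucose_mg_dl[tr_pid$time_s > 160]))
  expect_gt(osc_pid, 10 * osc_smc)
  # pinned negative result: the LQR loop on this heavily low-pass plant
  # suppresses the matched disturbance below SMC's switching ripple, so the
  # folklore ordering "SMC rejects better than LQR" does not show up in the
  # steady-state oscillation on the printed model
  lqr <- lqr_design(plant, reference_lqr_weights()$Q, 1)
  tr_lqr <- simulate_closed_loop(plant, lqr, cfgd)
  osc_lqr <- diff(range(tr_lqr$glucose_mg_dl[tr_lqr$time_s > 160]))
  expect_lt(osc_lqr, osc_smc)
  expect_lt(osc_lqr, 1e-4)
})

test_that("low-pass filtering strictly reduces the sliding-mode switching ripple", {
  plant <- ref_plant()
  smc <- reference_smc_params(plant = plant)
  # the first-order (Euler) stepping resolves the finite-frequency switching
  # ripple; the RK4 substage averaging suppresses it almost completely
  tr <- simulate_closed_loop(plant, smc,
                             simulation_config(dt = 0.01, horizon = 100,
                                               integrator = "euler"))
  before <- chattering_index(tr)
  expect_gt(before$amplitude, 1)        # switching is visible in u
  expect_gt(before$rate, 10)
  filtered <- tr
  filtered$control_u <- low_pass_filter(tr$control_u, dt = 0.01, cutoff = 2)
  after <- chattering_index(filtered)
  expect_gt(before$amplitude, after$amplitude)
  expect_lte(after$rate, before$rate)
  # the RK4 run realizes near-ideal sliding: ripple orders of magnitude lower
  tr_rk <- simulate_closed_loop(plant, smc,
                                simulation_config(dt = 0.01, horizon = 100))
  expect_lt(chattering_index(tr_rk)$amplitude, before$amplitude / 100)
})

test_that("divergence aborts with the blow-up time in the message", {
  unstable <- printed_state_space(domain = "continuous")
  expect_error(
    simulate_closed_loop(unstable, reference_pid_gains(),
                         simulation_config(dt = 0.1, horizon = 1000)),
    "diverged.*t = ")
})

test_that("controller comparison preserves order, is deterministic and survives per-row failures", {
  plant <- ref_plant()
  ctrls <- list(lqr = lqr_design(plant, reference_lqr_weights()$Q, 1),
                smc = reference_smc_params(plant = plant))
  cfg <- simulation_config(dt = 0.01, horizon = 120)
  r1 <- compare_controllers(plant, ctrls, cfg)
  r2 <- compare_controllers(plant, ctrls, cfg)
  expect_identical(r1, r2)
  expect_identical(r1$controller, c("lqr", "smc"))
  expect_true(all(is.na(r1$error)))
  # open-loop row on its own
  solo <- compare_controllers(plant, list(none = NULL),
                              simulation_config(dt = 10, horizon = 100000))
  expect_identical(nrow(solo), 1L)
  expect_false(is.na(solo$settling_time_s))
  # a diverging row is annotated, not fatal
  bad_plant <- printed_state_space(domain = "continuous")
  rb <- compare_controllers(bad_plant,
                            list(pid = reference_pid_gains(), none = NULL),
                            simulation_config(dt = 0.1, horizon = 2000))
  expect_false(is.na(rb$error[1]))
})

test_that("simulation config validates its fields", {
  expect_error(simulation_config(dt = 0), "dt")
  expect_error(simulation_config(horizon = 0.1), "horizon")
  expect_error(simulation_config(settling_band = 1.5), "settling_band")
  expect_error(simulation_config(G_ref = -5), "positive")
})
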