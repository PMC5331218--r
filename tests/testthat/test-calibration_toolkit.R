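test_that("ratio estimators are the stated quotients", {
  # matched sim threshold 0.7x over nominal 0.5x -> beta/alpha = 1.4
  expect_equal(estimate_beta_over_alpha(0.5, 0.7), 1.4)
  expect_equal(estimate_beta_over_alpha(0.5, 0.5), 1.0)
  expect_equal(estimate_beta_over_alpha(0.5, 1.0), 2.0)
  expect_error(estimate_beta_over_alpha(0, 0.7))
  expect_equal(estimate_gamma_over_alpha(0.8, 1.0), 0.8)
  expect_equal(estimate_gamma_over_alpha(0.44, 1.0), 0.44)
  expect_equal(estimate_gamma_over_alpha(0.9, 0.9), 1.0)
  expect_error(estimate_gamma_over_alpha(0.8, 0), "reference")
})

test_that("threshold bounds bracket the stated ideal values", {
  ideal <- calibration_state(beta_over_alpha = 1)
  b_or <- threshold_bounds(2, "OR", ideal)
  expect_lt(b_or[["lower"]], 0.6); expect_gt(b_or[["upper"]], 0.6)
  b_and <- threshold_bounds(2, "AND", ideal)
  expect_equal(b_and[["lower"]], 1.2) # inclusive boundary
  expect_gte(b_and[["upper"]], 1.2)
  # with beta/alpha = 1.4 the interval contains the chosen 0.85 within
  # a 0.05 rounding margin
  b14 <- threshold_bounds(2, "AND", calibration_state(beta_over_alpha = 1.4))
  expect_lt(b14[["lower"]], 0.85 + 0.05)
  expect_gt(b14[["upper"]], 0.85)
  # wide OR gates have no admissible threshold
  expect_error(threshold_bounds(5, "OR", ideal), "empty admissible")
})

test_that("the simple nominal-threshold adjustment divides by beta/alpha", {
  st <- calibration_state(beta_over_alpha = 1.4)
  expect_equal(adjust_threshold_simple(1.2, st), 1.2 / 1.4)
  expect_equal(adjust_threshold_simple(0.6, st), 0.6 / 1.4)
  expect_equal(adjust_threshold_simple(0.85,
                                       calibration_state(beta_over_alpha = 1)),
               0.85)
})

test_that("gate nominals are rescaled only below the 0.8 acceptance floor", {
  expect_equal(adjust_gate_nominals(c(1, 2), 0.8), c(1, 2))
  expect_equal(adjust_gate_nominals(c(1, 2), 0.9), c(1, 2))
  expect_equal(adjust_gate_nominals(1, 0.4), 2)
  expect_equal(adjust_gate_nominals(1.5, 0.5), 1.5 * 0.8 / 0.5)
})

test_that("outlier adjustment rescales by common over own ratio", {
  # the measured outlier gate: common 0.8 vs its own 0.44
  expect_equal(adjust_outlier(1, 0.8, 0.44), 0.8 / 0.44, tolerance = 1e-12)
  expect_equal(adjust_outlier(1, 0.8, 0.8), 1)
  # threshold outlier: ratio 2.8 vs common 1.4 halves the nominal
  expect_equal(adjust_outlier(0.85, 1.4, 2.8), 0.425)
})

test_that("delta range reproduces the printed 0.08-0.41 interval on a built fixture", {
  t1 <- 6; t2 <- 10
  on_par <- logistic_through(t1, 0.7, t2, 0.9)
  off_par <- logistic_through(t1, 0.38, t2, 0.51, y1 = 0.6)
  traj <- synthetic_trajectories(list(
    c(list(name = "on", y0 = 0, y1 = 1), on_par),
    c(list(name = "off", y0 = 0, y1 = 0.6), off_par)),
    times = seq(0, 24, by = 0.02))
  d <- delta_range(traj, "on", "off")
  expect_equal(unname(d["low"]), 0.08, tolerance = 1e-3)
  expect_equal(unname(d["high"]), 0.41, tolerance = 1e-3)
})

test_that("delta range edge cases: ideal OFF, sub-ideal OFF, partial records", {
  t1 <- 6; t2 <- 10
  on_par <- logistic_through(t1, 0.7, t2, 0.9)
  # OFF passing exactly through the ideal bounds gives (0, 0)
  off0 <- logistic_through(t1, 0.3, t2, 0.1, y0 = 0.32, y1 = 0.05)
  traj <- synthetic_trajectories(list(
    c(list(name = "on", y0 = 0, y1 = 1), on_par),
    c(list(name = "off", y0 = 0.32, y1 = 0.05), off0)),
    times = seq(0, 24, by = 0.02))
  d <- delta_range(traj, "on", "off")
  expect_equal(unname(d["low"]), 0, tolerance = 1e-3)
  expect_equal(unname(d["high"]), 0, tolerance = 1e-3)
  # an OFF below ideal at both crossings yields negative deltas
  traj$off2 <- 0.05
  d2 <- delta_range(traj, "on", "off2")
  expect_lt(d2[["low"]], 0); expect_lt(d2[["high"]], 0)
  # ON reaching 0.7 but not 0.9: partial result
  traj$on_slow <- 0.75 * traj$on
  d3 <- delta_range(traj, "on_slow", "off")
  expect_true(is.na(d3[["high"]]))
  expect_true(isTRUE(attr(d3, "partial")))
  # ON never reaching 0.7: no adjustment computable
  traj$on_dead <- 0.5 * traj$on
  expect_error(delta_range(traj, "on_dead", "off"), "never reaches 0.7")
})

test_that("output-threshold tuning adds delta * alpha/beta and is monotone", {
  st <- calibration_state(beta_over_alpha = 1.4)
  expect_equal(tune_output_threshold(0.85, 0.41, st), 0.85 + 0.41 / 1.4)
  expect_equal(tune_output_threshold(0.35, 0.08, st), 0.35 + 0.08 / 1.4)
  expect_equal(tune_output_threshold(0.85, 0, st), 0.85) # identity at 0
  deltas <- seq(0, 0.4, by = 0.05)
  vals <- vapply(deltas, function(d) tune_output_threshold(1, d, st),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(tune_output_threshold(0.85, -0.1, st), "non-negative")
})

test_that("tuning is refused when OFF trajectories are not slower than ON", {
  st <- calibration_state(beta_over_alpha = 1.4)
  traj <- synthetic_trajectories(list(
    list(name = "on", y0 = 0, y1 = 1, t50 = 10, tau = 1),
    list(name = "off", y0 = 0, y1 = 1, t50 = 4, tau = 1)))
  expect_error(tune_output_threshold(0.85, 0.2, st, traj = traj,
                                     on_rails = "on", off_rails = "off"),
               "refused")
  # and accepted when ON leads
  ok <- tune_output_threshold(0.85, 0.2, st,
                              traj = synthetic_trajectories(list(
                                list(name = "on", y0 = 0, y1 = 1, t50 = 4,
                                     tau = 1),
                                list(name = "off", y0 = 0, y1 = 0.5,
                                     t50 = 14, tau = 1))),
                              on_rails = "on", off_rails = "off")
  expect_equal(ok, 0.85 + 0.2 / 1.4)
})

test_that("the flowchart advisor reproduces the systematic procedure", {
  a <- advise_next_step(list(stage = "restoration", beta_over_alpha = 1.4))
  expect_equal(a$action, "adjust_all_thresholds")
  a <- advise_next_step(list(stage = "restoration", beta_over_alpha = 1.1))
  expect_equal(a$action, "proceed_single_gate")
  a <- advise_next_step(list(stage = "single_gate", correct = FALSE))
  expect_equal(a$action, "recalibrate_gate_threshold")
  a <- advise_next_step(list(stage = "single_gate", correct = TRUE))
  expect_equal(a$action, "proceed_gate_calibration")
  a <- advise_next_step(list(stage = "gate_calibration",
                             gamma_over_alpha = 0.8))
  expect_equal(a$action, "proceed_two_layer") # 0.8 is not below the floor
  a <- advise_next_step(list(stage = "gate_calibration",
                             gamma_over_alpha = 0.44))
  expect_equal(a$action, "adjust_all_gates")
  a <- advise_next_step(list(stage = "two_layer", outlier = "g_22_53"))
  expect_equal(a$action, "recalibrate_outlier_gate")
  a <- advise_next_step(list(stage = "two_layer", outlier = FALSE,
                             separation_ok = FALSE, on_faster = TRUE))
  expect_equal(a$action, "increase_output_threshold")
  a <- advise_next_step(list(stage = "two_layer", outlier = FALSE,
                             separation_ok = TRUE))
  expect_equal(a$action, "proceed_larger_circuit")
  a <- advise_next_step(list(stage = "larger_circuit", correct = FALSE))
  expect_equal(a$action, "identify_worst_outlier")
  a <- advise_next_step(list(stage = "larger_circuit", correct = TRUE))
  expect_equal(a$action, "done")
  expect_error(advise_next_step(list(stage = "annealing")), "unknown stage")
})

test_that("beta/alpha is recovered within 5% from simulated restoration data", {
  for (rho in c(1.0, 1.2, 1.4, 1.8)) {
    observed <- simulate_restoration(c(0.3, 0.7), threshold_x = 0.5,
                                     threshold_scale = rho, t_end_h = 10,
                                     n_out = 41)
    matched <- match_sim_threshold(observed, 0.5)
    est <- estimate_beta_over_alpha(0.5, matched)
    expect_equal(est, rho, tolerance = 0.05)
  }
})

test_that("gamma/alpha is recovered from simulated fully-triggered gates", {
  for (g in c(0.44, 0.8, 1.0)) {
    r <- simulate_gate_calibration(gamma = g)
    expect_equal(estimate_gamma_over_alpha(r$triggered, r$reference), g,
                 tolerance = 1e-3)
  }
})

test_that("calibration plus output tuning improves a noisy two-layer circuit", {
  # two-layer AND of ORs, unpurified model plus a 5% strand-stoichiometry
  # excess; ON case both ORs high, hard OFF case one OR high
  ckt <- two_layer_circuit()
  separation <- function(ssc) {
    vals <- lapply(c(on = "1010", off = "1100"), function(bits) {
      net <- build_purified_crn(ssc, inputs = bits,
                                excess_signal_frac = 0.05)
      net <- expand_crn(net, error_model_config(r = 0.01))
      comp <- reporter_completion(net, simulate_crn(net, t_end_h = 24,
                                                    n_out = 97))
      attr(comp, "expected") <- expected_rail_states(ssc, bits)
      comp
    })
    # worst-case separation on the ON rail at read time, normalized
    # against the ON run's plateau
    on_run <- normalize_trajectories(vals$on, off_ref = "y__0",
                                     on_ref = "y__1")
    scale <- mean(tail(vals$on$y__1, 5))
    tail(on_run$y__1, 1) - tail(vals$off$y__1, 1) / scale
  }
  plain <- compile_seesaw(to_dual_rail(ckt))
  tuned <- experimental_concentrations(compile_seesaw(to_dual_rail(ckt)))
  expect_gt(separation(tuned), separation(plain))
})
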