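test_that("the purified network contains the expected reaction inventory", {
  ssc <- compile_seesaw(to_dual_rail(passthrough_circuit()))
  net <- build_purified_crn(ssc)
  rates <- rate_config()
  ty <- table(net$reactions$type)
  # per fan-out node: input x (consumer output + fuel) = 2 reversible
  # seesaw pairs = 4 reactions; 1 thresholding; 2 blunt-end leaks
  expect_equal(unname(ty[["seesawing"]]), 8)
  expect_equal(unname(ty[["thresholding"]]), 2)
  expect_equal(unname(ty[["leak"]]), 4)
  expect_equal(unname(ty[["reporting"]]), 2)
  # occlusion: one on/off pair per free strand (2 inputs, 2 wire signals,
  # 2 fuels)
  expect_equal(unname(ty[["binding_on"]]), 6)
  expect_equal(unname(ty[["binding_off"]]), 6)
  rx <- net$reactions
  expect_true(all(rx$rate[rx$type == "seesawing"] == rates$k_s))
  expect_true(all(rx$rate[rx$type == "thresholding"] == rates$k_f))
  expect_true(all(rx$rate[rx$type == "leak"] == rates$k_l))
  expect_true(all(rx$rate[rx$type == "binding_off"] == rates$k_rs))
})

test_that("every seesawing reaction has its reverse at the same rate", {
  net <- build_purified_crn(compile_seesaw(to_dual_rail(single_and_circuit())))
  rx <- net$reactions
  ss <- rx[rx$type == "seesawing", ]
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  fwd <- paste(mapply(key, ss$r1, ss$r2), mapply(key, ss$p1, ss$p2), ss$rate)
  rev <- paste(mapply(key, ss$p1, ss$p2), mapply(key, ss$r1, ss$r2), ss$rate)
  expect_setequal(fwd, rev)
})

test_that("strand moieties are conserved and concentrations stay positive", {
  ssc <- compile_seesaw(to_dual_rail(rule_circuit()),
                        compiler_config(std_conc_nM = 100))
  net <- build_purified_crn(ssc, inputs = "011")
  traj <- simulate_crn(net, t_end_h = 12)
  expect_lt(moiety_drift(net, traj), 1e-6)
  expect_gt(min(as.matrix(traj[, -1])), -1e-6)
})

test_that("pure bimolecular dynamics are invariant under conc x2, rate /2", {
  ssc1 <- compile_seesaw(to_dual_rail(single_and_circuit()),
                         compiler_config(std_conc_nM = 100))
  ssc2 <- compile_seesaw(to_dual_rail(single_and_circuit()),
                         compiler_config(std_conc_nM = 200))
  r1 <- rate_config()
  r2 <- rate_config(k_f = r1$k_f / 2, k_s = r1$k_s / 2, k_l = r1$k_l / 2,
                    k_rep = r1$k_rep / 2)
  n1 <- build_purified_crn(ssc1, r1, inputs = "11", binding = FALSE)
  n2 <- build_purified_crn(ssc2, r2, inputs = "11", binding = FALSE)
  c1 <- reporter_completion(n1, simulate_crn(n1, t_end_h = 6))
  c2 <- reporter_completion(n2, simulate_crn(n2, t_end_h = 6))
  expect_equal(c1$y__1, c2$y__1, tolerance = 1e-6)
})

test_that("normalization maps the OFF start to 0 and the ON plateau to 1", {
  traj <- synthetic_trajectories(list(
    list(name = "on", y0 = 0.1, y1 = 0.9, t50 = 5, tau = 1),
    list(name = "off", y0 = 0.12, y1 = 0.25, t50 = 8, tau = 2)))
  nrm <- normalize_trajectories(traj, off_ref = "off", on_ref = "on")
  expect_equal(nrm$off[1], 0)
  expect_equal(mean(tail(nrm$on, 5)), 1)
  # a constant trajectory equal to the OFF start normalizes to all zeros
  traj$flat <- traj$off[1]
  nrm2 <- normalize_trajectories(traj, "off", "on")
  expect_true(all(abs(nrm2$flat) < 1e-12))
  # a known affine distortion is inverted exactly
  distorted <- traj
  for (cl in c("on", "off")) distorted[[cl]] <- 3.7 * traj[[cl]] + 0.42
  expect_equal(normalize_trajectories(distorted, "off", "on")$on, nrm$on,
               tolerance = 1e-12)
  # degenerate references are rejected
  flat <- traj; flat$on <- 0.5; flat$off <- 0.5
  expect_error(normalize_trajectories(flat, "off", "on"), "degenerate")
})

test_that("logic outcome applies the 0.7/0.3 separation bands", {
  traj <- synthetic_trajectories(list(
    list(name = "a", y0 = 0, y1 = 0.95, t50 = 3, tau = 0.5),
    list(name = "b", y0 = 0, y1 = 0.1, t50 = 3, tau = 0.5),
    list(name = "c", y0 = 0, y1 = 0.65, t50 = 3, tau = 0.5)))
  expect_true(logic_outcome(traj, c(a = 1, b = 0))$correct)
  # an ON rail at 0.65 fails the 0.7 floor
  expect_false(logic_outcome(traj, c(c = 1, b = 0))$correct)
  # swapping expectations complements correctness on separable data
  expect_false(logic_outcome(traj, c(a = 0, b = 1))$correct)
  expect_error(logic_outcome(traj, c(zz = 1)), "missing rail")
})

test_that("completion time interpolates the first crossing of the slowest rail", {
  traj <- synthetic_trajectories(list(
    list(name = "fast", y0 = 0, y1 = 1, t50 = 2, tau = 0.3),
    list(name = "slow", y0 = 0, y1 = 1, t50 = 6, tau = 0.3),
    list(name = "high", y0 = 0.8, y1 = 0.95, t50 = 1, tau = 0.5),
    list(name = "never", y0 = 0, y1 = 0.4, t50 = 2, tau = 0.5)))
  ct <- completion_time(traj, c("fast", "slow"), level = 0.5)
  expect_equal(ct, 6, tolerance = 0.01)
  expect_equal(completion_time(traj, "high"), 0) # starts above the level
  expect_true(is.na(completion_time(traj, c("fast", "never"))))
})

test_that("signal restoration cleans sub-threshold and amplifies supra-threshold inputs", {
  tr <- simulate_restoration(c(0.3, 0.7), threshold_x = 0.5, t_end_h = 10)
  expect_lt(tail(tr$in_0.3, 1), 0.2)
  expect_gt(tail(tr$in_0.7, 1), 0.8)
})

test_that("raising the threshold never speeds up the downstream ON signal", {
  read_h <- 4
  levels <- c(0.2, 0.4, 0.6, 0.8)
  vals <- vapply(levels, function(th) {
    tr <- simulate_restoration(0.9, threshold_x = th, t_end_h = read_h,
                               n_out = 41)
    tail(tr$in_0.9, 1)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("the ideal-model simulation computes the demonstration circuit correctly", {
  # spot-check one input end to end through the high-level interface
  ssc <- compile_seesaw(to_dual_rail(rule_circuit()),
                        compiler_config(std_conc_nM = 50))
  traj <- simulate_circuit(ssc, "001", t_end_h = 24)
  oc <- logic_outcome(traj)
  expect_true(oc$correct)
  expect_gt(oc$values[["R110__1"]], 0.7) # rule 110 of LCR=001 is 1
  expect_lt(oc$values[["R124__1"]], 0.3) # rule 124 of LCR=001 is 0
})
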