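# Frozen expectations below were computed from the closed-form binomial
# expressions directly: choose(l,n) r^n (1-r)^(l-n) with l = 35, r = 0.01
# gives 0.99^35 = 0.7034477, 15*0.01*0.99^34 = 0.1065830 and
# 5*0.01*0.99^34 = 0.03552766; the inert remainder is 0.0478587.

test_that("the binomial synthesis-error probability matches the closed form", {
  closed_form <- function(l, n, r) choose(l, n) * r^n * (1 - r)^(l - n)
  for (l in c(15, 25, 35)) for (n in 0:3) {
    expect_equal(error_prob(l, n, 0.01), closed_form(l, n, 0.01),
                 tolerance = 1e-12)
  }
  expect_equal(error_prob(35, 0, 0.01), 0.7034477, tolerance = 1e-6)
  expect_equal(error_prob(35, 0, 0), 1)
  expect_equal(error_prob(35, 2, 0), 0)
  expect_equal(sum(error_prob(35, 0:35, 0.01)), 1, tolerance = 1e-12)
  expect_error(error_prob(10, 11, 0.01), "exceed")
})

test_that("domain-resolved error probabilities follow the printed formula", {
  cfg <- error_model_config(r = 0.01)
  expect_equal(domain_error_prob(1, 0, cfg), 0.1065830, tolerance = 1e-6)
  expect_equal(domain_error_prob(0, 0, cfg), error_prob(35, 0, 0.01),
               tolerance = 1e-12) # consistency identity
  cfg0 <- error_model_config(r = 0)
  expect_equal(domain_error_prob(0, 0, cfg0), 1)
  expect_equal(domain_error_prob(1, 0, cfg0), 0)
  expect_error(domain_error_prob(16, 0, cfg), "out of range")
})

test_that("signal strands partition into the five stated populations", {
  pop <- partition_species("s_1_2", error_model_config(r = 0.01))
  expect_equal(nrow(pop), 5) # error-free, bm1, toehold, bm2, inert
  frac <- setNames(pop$fraction, pop$variant)
  expect_equal(unname(frac["ef"]), 0.7034477, tolerance = 1e-6)
  expect_equal(unname(frac["s_1_2.bm1"]), 0.1065830, tolerance = 1e-6)
  expect_equal(unname(frac["s_1_2.th"]), 0.03552766, tolerance = 1e-6)
  expect_equal(unname(frac["s_1_2.bm2"]), 0.1065830, tolerance = 1e-6)
  expect_equal(unname(frac["inert"]), 0.0478587, tolerance = 1e-6)
  expect_equal(sum(pop$fraction), 1, tolerance = 1e-12)
})

test_that("population fractions sum to one for every species of the network", {
  net <- build_purified_crn(compile_seesaw(to_dual_rail(rule_circuit())))
  pops <- error_populations(net, error_model_config(r = 0.01))
  for (pop in pops) expect_equal(sum(pop$fraction), 1, tolerance = 1e-12)
  # threshold complexes: ef + 3 bottom domains + 1 top domain + inert
  th_id <- net$species$id[net$species$role == "threshold"][1]
  expect_equal(nrow(pops[[th_id]]), 6)
  # r = 0 collapses to a single error-free population
  pop0 <- partition_species("s_1_2", error_model_config(r = 0))
  expect_equal(pop0$fraction[pop0$variant == "ef"], 1)
  expect_true(all(abs(pop0$fraction[pop0$variant != "ef"]) < 1e-15))
})

test_that("expansion conserves total initial concentration per species", {
  net <- build_purified_crn(compile_seesaw(to_dual_rail(single_and_circuit())))
  ex <- expand_crn(net, error_model_config(r = 0.01))
  base <- setNames(net$species$init_x, net$species$id)
  for (id in names(base)) {
    vs <- ex$species$init_x[ex$species$id == id |
                              startsWith(ex$species$id, paste0(id, "~"))]
    expect_equal(sum(vs), base[[id]], tolerance = 1e-12)
  }
})

test_that("r = 0 expansion is exactly the purified network", {
  net <- build_purified_crn(compile_seesaw(to_dual_rail(single_and_circuit())))
  expect_identical(expand_crn(net, error_model_config(r = 0)), net)
})

test_that("error-free variant reactions reuse the base rates bit for bit", {
  net <- build_purified_crn(compile_seesaw(to_dual_rail(passthrough_circuit())))
  ex <- expand_crn(net, error_model_config(r = 0.01))
  base_key <- function(rx) paste(rx$r1, rx$r2, rx$p1, rx$p2)
  ef <- ex$reactions[!grepl("~", paste(ex$reactions$r1, ex$reactions$r2,
                                       ex$reactions$p1, ex$reactions$p2)), ]
  expect_setequal(paste(base_key(ef), ef$rate, ef$type),
                  paste(base_key(net$reactions), net$reactions$rate,
                        net$reactions$type))
})

test_that("slowdown rules follow the domain and reversibility classification", {
  rates <- rate_config()
  net <- build_purified_crn(compile_seesaw(to_dual_rail(passthrough_circuit())),
                            rates)
  ex <- expand_crn(net, error_model_config(r = 0.01, phi = 100))
  rx <- ex$reactions
  has_err <- function(col, dom) grepl(dom, col, fixed = TRUE)
  # reversible seesawing with a branch-migration error: k_s / 100
  ss_bm <- rx$type == "seesawing" &
    (has_err(rx$r1, ".bm") | has_err(rx$r2, ".bm")) &
    !(has_err(rx$r1, ".th") | has_err(rx$r2, ".th") |
        has_err(rx$r1, ".ext") | has_err(rx$r2, ".ext"))
  expect_gt(sum(ss_bm), 0)
  expect_true(all(rx$rate[ss_bm] == rates$k_s / 100))
  # irreversible thresholding with a branch-migration error: unchanged k_f
  th_bm <- rx$type == "thresholding" & has_err(rx$r1, ".bm1") &
    !grepl("~", rx$r2)
  expect_gt(sum(th_bm), 0)
  expect_true(all(rx$rate[th_bm] == rates$k_f))
  # a toehold error in the input signal slows thresholding 100-fold
  th_toe <- rx$type == "thresholding" & has_err(rx$r1, ".th")
  expect_gt(sum(th_toe), 0)
  expect_true(all(rx$rate[th_toe] == rates$k_f / 100))
  # occlusion release accelerates from k_rs to k_rf for toehold errors
  occ_toe <- rx$type == "binding_off" & has_err(rx$r1, ".th")
  expect_gt(sum(occ_toe), 0)
  expect_true(all(rx$rate[occ_toe] == rates$k_rf))
  occ_bm <- rx$type == "binding_off" & has_err(rx$r1, ".bm")
  expect_true(all(rx$rate[occ_bm] == rates$k_rs))
})

test_that("forcing single-error molecules inert truncates to scaled error-free populations", {
  net <- build_purified_crn(compile_seesaw(to_dual_rail(single_and_circuit())))
  ex <- expand_crn(net, error_model_config(r = 0.01,
                                           single_error_policy = "inert"))
  # reaction set identical to the purified network
  expect_equal(ex$reactions[c("r1", "r2", "p1", "p2", "rate", "type")],
               net$reactions[c("r1", "r2", "p1", "p2", "rate", "type")])
  # error-free initial concentrations scaled by P(0 errors)
  cfg <- error_model_config(r = 0.01)
  for (i in seq_len(nrow(net$species))) {
    id <- net$species$id[i]
    if (id %in% seesawr:::crn_sinks(net)) next
    p0 <- partition_species(net$composition[[id]], cfg)
    f <- p0$fraction[p0$variant == "ef"]
    expect_equal(ex$species$init_x[ex$species$id == id],
                 net$species$init_x[i] * f, tolerance = 1e-12)
  }
})

test_that("expanded trajectories converge monotonically to the purified limit", {
  ssc <- compile_seesaw(to_dual_rail(single_and_circuit()))
  net <- build_purified_crn(ssc, inputs = "11")
  ref <- reporter_completion(net, simulate_crn(net, t_end_h = 8, n_out = 49))
  sup <- vapply(c(1e-3, 1e-4), function(r) {
    ex <- expand_crn(net, error_model_config(r = r))
    comp <- reporter_completion(ex, simulate_crn(ex, t_end_h = 8, n_out = 49))
    max(abs(comp$y__1 - ref$y__1), abs(comp$y__0 - ref$y__0))
  }, numeric(1))
  expect_lt(sup[2], sup[1]) # smaller r, closer to purified
  expect_lt(sup[2], 0.02)
})

test_that("moiety conservation holds in the expanded network", {
  ssc <- compile_seesaw(to_dual_rail(passthrough_circuit()))
  net <- build_purified_crn(ssc, inputs = "1")
  ex <- expand_crn(net, error_model_config(r = 0.01))
  traj <- simulate_crn(ex, t_end_h = 8, n_out = 25)
  expect_lt(moiety_drift(ex, traj), 1e-6)
})

test_that("synthesis errors slow circuit completion", {
  ssc <- compile_seesaw(to_dual_rail(single_and_circuit()))
  net <- build_purified_crn(ssc, inputs = "11")
  cp <- reporter_completion(net, simulate_crn(net, t_end_h = 24))
  attr(cp, "expected") <- expected_rail_states(ssc, "11")
  ex <- expand_crn(net, error_model_config(r = 0.01))
  cu <- reporter_completion(ex, simulate_crn(ex, t_end_h = 24))
  attr(cu, "expected") <- expected_rail_states(ssc, "11")
  t_pur <- completion_time(normalize_by_expectation(cp))
  t_unp <- completion_time(normalize_by_expectation(cu))
  expect_gt(t_unp, t_pur)
})
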