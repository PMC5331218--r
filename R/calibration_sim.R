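#' Simulate a digital signal-restoration experiment
#'
#' The simplest functional component: one input fan-out node (threshold +
#' gate:output + fuel) feeding a reporter, i.e. the compiled passthrough
#' circuit. Inputs below the threshold are cleaned up towards OFF by the
#' fast thresholding reaction; inputs above it are amplified towards ON by
#' fuel-driven catalysis.
#'
#' @param input_x Input concentration(s) in x units (one trajectory per
#'   value).
#' @param threshold_x Nominal threshold concentration (x units).
#' @param threshold_scale Effective-to-nominal multiplier applied to the
#'   threshold's initial concentration (emulates an unpurified threshold
#'   whose effective concentration exceeds nominal by beta/alpha).
#' @param t_end_h Duration (hours).
#' @param rates A [rate_config()].
#' @param std_conc_nM Standard concentration 1x (nM).
#' @param n_out Output time points.
#' @return A `seesaw_traj`: `time` plus one completion column per input
#'   value, named `in_<value>`.
#' @export
simulate_restoration <- function(input_x, threshold_x = 0.5,
                                 threshold_scale = 1, t_end_h = 10,
                                 rates = rate_config(), std_conc_nM = 100,
                                 n_out = 121) {
  ckt <- parse_netlist(c("input x", "output y = x"))
  ssc <- compile_seesaw(ckt, compiler_config(std_conc_nM = std_conc_nM))
  th_on <- ssc$species$role == "threshold"
  ssc$species$conc_x[th_on] <- threshold_x
  out <- NULL
  for (v in input_x) {
    net <- build_purified_crn(ssc, rates)
    # isolate the ON rail: drive x__1 with the probed input, silence x__0
    net$species$init_x[net$species$id ==
                         ssc$input_species[["x__1"]]] <- v
    net$species$init_x[net$species$id ==
                         ssc$input_species[["x__0"]]] <- 0
    net$species$init_x[net$species$id %in%
                         ssc$species$id[th_on]] <-
      threshold_x * threshold_scale
    traj <- simulate_crn(net, t_end_h = t_end_h, n_out = n_out)
    comp <- reporter_completion(net, traj)
    if (is.null(out)) out <- data.frame(time = comp$time)
    out[[sprintf("in_%g", v)]] <- comp[["y__1"]]
  }
  structure(out, class = c("seesaw_traj", "data.frame"))
}

#' Estimate the matched simulation threshold for observed restoration data
#'
#' Sweeps the simulated threshold concentration (1-D optimization of the
#' trajectory sum of squares) until the simulation reproduces the observed
#' signal-restoration trajectories; the matched threshold divided by the
#' nominal threshold is the beta/alpha estimate.
#'
#' @param observed A `seesaw_traj` from a restoration experiment (columns
#'   `in_<value>` as produced by [simulate_restoration()]).
#' @param nominal_threshold_x The nominal threshold of the experiment.
#' @param input_x The input values probed.
#' @param interval Search interval for the effective/nominal multiplier.
#' @param ... Passed to [simulate_restoration()] (rates, standard
#'   concentration, duration).
#' @return The matched simulation threshold (x units).
#' @export
match_sim_threshold <- function(observed, nominal_threshold_x,
                                input_x = c(0.3, 0.7),
                                interval = c(0.5, 3), ...) {
  t_end_h <- max(observed$time)
  sse <- function(scale) {
    sim <- simulate_restoration(input_x, threshold_x = nominal_threshold_x,
                                threshold_scale = scale, t_end_h = t_end_h,
                                n_out = 61, ...)
    s <- 0
    for (v in input_x) {
      col <- sprintf("in_%g", v)
      s <- s + sum((approx(sim$time, sim[[col]], xout = observed$time,
                           rule = 2)$y - observed[[col]])^2)
    }
    s
  }
  fit <- optimize(sse, interval, tol = 1e-3)
  fit$minimum * nominal_threshold_x
}

#' Simulate a gate-calibration (fully triggered gate) experiment
#'
#' Compares the fully triggered output of a gate:output species with a
#' reference gate of the same nominal concentration, with excess input so
#' release is complete; the plateau ratio estimates gamma/alpha.
#'
#' @param gamma Effective-to-nominal multiplier applied to the probed
#'   gate:output's initial concentration.
#' @param t_end_h Duration (hours); long enough for full triggering.
#' @param rates,std_conc_nM As in [simulate_restoration()].
#' @return List with the probed plateau (`triggered`), the reference
#'   plateau (`reference`) and the trajectories.
#' @export
simulate_gate_calibration <- function(gamma = 1, t_end_h = 12,
                                      rates = rate_config(),
                                      std_conc_nM = 100) {
  run <- function(g_scale) {
    ckt <- parse_netlist(c("input x", "output y = x"))
    cfg <- compiler_config(std_conc_nM = std_conc_nM, input_on = 2,
                           fanout_threshold = 0.05)
    ssc <- compile_seesaw(ckt, cfg)
    net <- build_purified_crn(ssc, rates)
    net$species$init_x[net$species$id ==
                         ssc$input_species[["x__0"]]] <- 0
    gid <- ssc$species$id[ssc$species$role == "gate_output" &
                            ssc$species$node ==
                            ssc$species$node[ssc$species$id ==
                                               ssc$input_species[["x__1"]]]]
    net$species$init_x[net$species$id %in% gid] <-
      net$species$init_x[net$species$id %in% gid] * g_scale
    traj <- simulate_crn(net, t_end_h = t_end_h, n_out = 61)
    reporter_completion(net, traj)[["y__1"]]
  }
  probe <- run(gamma)
  ref <- run(1)
  list(triggered = tail(probe, 1), reference = tail(ref, 1),
       probe_traj = probe, reference_traj = ref)
}
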