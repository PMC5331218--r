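#' Calibration state for unpurified-circuit construction
#'
#' Holds the measured effective-to-nominal concentration ratios that drive
#' every adjustment: `beta/alpha` (threshold to signal; 1.4 is the value
#' consistently measured for unpurified strands), `gamma/alpha` (gate to
#' signal; commonly 0.8), per-species outlier ratios, and the output-tuning
#' `delta` range.
#'
#' @param beta_over_alpha Threshold-to-signal effective ratio.
#' @param gamma_over_alpha Gate-to-signal effective ratio.
#' @param outliers Named numeric: species id -> its own measured ratio.
#' @param delta Optional `c(low, high)` ON/OFF separation deficit range.
#' @return A `calibration_state` list.
#' @export
calibration_state <- function(beta_over_alpha = 1.4, gamma_over_alpha = 0.8,
                              outliers = numeric(), delta = NULL) {
  stopifnot(beta_over_alpha > 0, gamma_over_alpha > 0)
  if (!is.null(delta)) stopifnot(length(delta) == 2, delta[1] <= delta[2])
  structure(list(beta_over_alpha = beta_over_alpha,
                 gamma_over_alpha = gamma_over_alpha,
                 outliers = outliers, delta = delta,
                 off_band = c(0, 0.2), on_band = c(0.8, 1),
                 sep_lower = c(on = 0.7, off = 0.3),
                 sep_upper = c(on = 0.9, off = 0.1)),
            class = "calibration_state")
}

#' Threshold-to-signal ratio from a matched simulation
#'
#' The effective threshold surplus of unpurified molecules is estimated by
#' finding the simulated threshold concentration that reproduces the
#' observed signal-restoration data; the ratio is then
#' `matched_sim_threshold / nominal_threshold`.
#'
#' @param nominal_threshold Nominal threshold concentration (x units).
#' @param matched_sim_threshold Simulation threshold that matched the data.
#' @return The ratio beta/alpha.
#' @export
estimate_beta_over_alpha <- function(nominal_threshold, matched_sim_threshold) {
  stopifnot(nominal_threshold > 0, matched_sim_threshold > 0)
  matched_sim_threshold / nominal_threshold
}

#' Gate-to-signal ratio from a fully-triggered-gate experiment
#'
#' Compares the fully triggered concentration of a gate with a reference
#' signal at the same nominal concentration.
#'
#' @param triggered_gate_level Normalized fully-triggered gate output.
#' @param reference_signal_level Normalized reference signal level.
#' @return The ratio gamma/alpha.
#' @export
estimate_gamma_over_alpha <- function(triggered_gate_level,
                                      reference_signal_level) {
  if (reference_signal_level <= 0) stop("reference signal level must be > 0")
  triggered_gate_level / reference_signal_level
}

#' Nominal threshold bounds for an n-input logic gate
#'
#' From the ideal OFF = \[0, 0.2\] and ON = \[0.8, 1\] bands of the
#' integrating sum: an OR threshold must consume the largest all-OFF sum
#' (`0.2 n`) but pass a single ON input (`0.8`); an AND threshold must
#' consume the largest sum with one OFF input (`n - 0.8`) but pass the
#' smallest all-ON sum (`0.8 n`). Effective bounds are converted to
#' nominal by dividing by beta/alpha.
#'
#' @param n Gate fan-in.
#' @param gate_type `"AND"` or `"OR"`.
#' @param ratios A [calibration_state()] (its `beta_over_alpha` is used).
#' @return `c(lower, upper)` nominal threshold in x units.
#' @export
threshold_bounds <- function(n, gate_type = c("AND", "OR"),
                             ratios = calibration_state(beta_over_alpha = 1)) {
  gate_type <- match.arg(gate_type)
  stopifnot(n >= 1)
  eff <- switch(gate_type,
                OR = c(lower = 0.2 * n, upper = 0.8),
                AND = c(lower = n - 0.8, upper = 0.8 * n))
  if (eff["lower"] > eff["upper"])
    stop(sprintf("empty admissible threshold interval for %d-input %s",
                 n, gate_type))
  eff / ratios$beta_over_alpha
}

#' Simple nominal-threshold adjustment
#'
#' The less flexible but simpler alternative to choosing within the
#' bounds: divide the ideal threshold by the threshold-to-signal ratio.
#'
#' @param ideal_threshold Ideal (beta/alpha = 1) threshold in x units.
#' @param ratios A [calibration_state()].
#' @return Nominal threshold in x units.
#' @export
adjust_threshold_simple <- function(ideal_threshold,
                                    ratios = calibration_state()) {
  stopifnot(ideal_threshold > 0)
  ideal_threshold / ratios$beta_over_alpha
}

#' Gate-concentration adjustment for low gate-to-signal ratios
#'
#' No adjustment is made when gamma/alpha >= 0.8, because the signal
#' restoration built into every logic gate accepts an ON state of
#' \[0.8, 1\]. Below that, gate nominal concentrations are rescaled by
#' `0.8 / (gamma/alpha)` so the effective gate concentration re-enters the
#' acceptable ON band.
#'
#' @param gate_nominals Numeric vector of nominal gate concentrations
#'   (x units).
#' @param gamma_over_alpha Measured gate-to-signal ratio.
#' @return Adjusted nominal concentrations.
#' @export
adjust_gate_nominals <- function(gate_nominals, gamma_over_alpha) {
  stopifnot(gamma_over_alpha > 0)
  if (gamma_over_alpha >= 0.8) return(gate_nominals)
  gate_nominals * 0.8 / gamma_over_alpha
}

#' Outlier nominal-concentration adjustment
#'
#' Once a threshold or gate species is identified as an outlier, its
#' nominal concentration is rescaled using its own measured ratio and the
#' common ratio of the other species of its kind:
#' `common_nominal * common_ratio / outlier_ratio`.
#'
#' @param common_nominal Common nominal concentration (x units).
#' @param common_ratio Common effective ratio (beta/alpha for thresholds,
#'   gamma/alpha for gates).
#' @param outlier_ratio The outlier's own measured ratio.
#' @return Adjusted nominal concentration.
#' @export
adjust_outlier <- function(common_nominal, common_ratio, outlier_ratio) {
  stopifnot(common_nominal > 0, common_ratio > 0, outlier_ratio > 0)
  common_nominal * common_ratio / outlier_ratio
}

#' ON/OFF separation deficit range (delta)
#'
#' When the ON reference trajectory first reaches the lower-bound ideal ON
#' value 0.7, the OFF reference's excess over the ideal OFF value 0.3
#' gives `delta_low`; when the ON reference reaches the upper-bound ideal
#' ON value 0.9, the OFF excess over 0.1 gives `delta_high`.
#'
#' @param traj A normalized `seesaw_traj`.
#' @param on_ref,off_ref Column names of the ON and OFF reference
#'   trajectories (rule of thumb: slowest ON, fastest OFF).
#' @return `c(low = , high = )`; `high` is `NA` with attribute
#'   `partial = TRUE` if the ON reference reaches 0.7 but never 0.9.
#' @export
delta_range <- function(traj, on_ref, off_ref) {
  stopifnot(on_ref %in% names(traj), off_ref %in% names(traj))
  t07 <- completion_time(traj, on_ref, level = 0.7)
  if (is.na(t07))
    stop("ON reference never reaches 0.7: no threshold adjustment computable")
  low <- traj_at(traj, off_ref, t07) - 0.3
  t09 <- completion_time(traj, on_ref, level = 0.9)
  if (is.na(t09)) {
    out <- c(low = low, high = NA_real_)
    attr(out, "partial") <- TRUE
    return(out)
  }
  c(low = low, high = traj_at(traj, off_ref, t09) - 0.1)
}

#' Tune the output threshold by the separation deficit
#'
#' Increases the nominal threshold of the logic gate producing the circuit
#' output by `delta * alpha/beta`, suppressing undesired OFF signal while
#' slowing the ON trajectories; only applicable when all ON trajectories
#' are significantly faster than all OFF trajectories, which is checked
#' when reference trajectories are supplied.
#'
#' @param current_nominal Current nominal output threshold (x units).
#' @param delta Chosen separation deficit (>= 0).
#' @param ratios A [calibration_state()].
#' @param traj,on_rails,off_rails Optional normalized trajectories and
#'   rail sets for the ON-faster-than-OFF precondition check.
#' @return New nominal threshold in x units.
#' @export
tune_output_threshold <- function(current_nominal, delta,
                                  ratios = calibration_state(),
                                  traj = NULL, on_rails = NULL,
                                  off_rails = NULL) {
  stopifnot(current_nominal > 0)
  if (delta < 0) stop("delta must be non-negative")
  if (!is.null(traj)) {
    on_t <- vapply(on_rails, function(r)
      completion_time(traj, r, level = 0.7), numeric(1))
    off_t <- vapply(off_rails, function(r) {
      ct <- completion_time(traj, r, level = 0.7)
      if (is.na(ct)) Inf else ct
    }, numeric(1))
    if (anyNA(on_t) || max(on_t) >= min(off_t))
      stop("output tuning refused: not all ON trajectories are faster than ",
           "all OFF trajectories; recalibrate thresholds/gates instead")
  }
  current_nominal + delta / ratios$beta_over_alpha
}

#' Next-step advisor for the systematic build procedure
#'
#' Deterministic decision engine for the incremental, bottom-up
#' construction of unpurified seesaw circuits: signal restoration first,
#' then a single logic gate, gate calibration, a two-layer circuit, and
#' finally larger circuits, with calibration/outlier/tuning loops at each
#' stage.
#'
#' @param state List describing the current stage and available
#'   measurements. `stage` is one of `"restoration"`, `"single_gate"`,
#'   `"gate_calibration"`, `"two_layer"`, `"larger_circuit"`. Optional
#'   fields by stage: `beta_over_alpha`; `correct` (logical);
#'   `gamma_over_alpha`; `outlier` (logical or species id);
#'   `separation_ok` (logical), `on_faster` (logical).
#' @return A `seesaw_advice`: list with `action` (machine-readable code)
#'   and `message`.
#' @export
advise_next_step <- function(state) {
  stage <- state$stage
  adv <- function(action, message)
    structure(list(stage = stage, action = action, message = message),
              class = "seesaw_advice")
  if (is.null(stage)) stop("state$stage is required")
  switch(
    stage,
    restoration = {
      boa <- state$beta_over_alpha
      if (is.null(boa)) stop("restoration stage needs beta_over_alpha")
      if (boa > 1.2)
        adv("adjust_all_thresholds",
            sprintf("threshold-to-signal ratio %.2f > 1.2: adjust the nominal thresholds in all logic gates (divide ideal thresholds by %.2f)", boa, boa))
      else adv("proceed_single_gate",
               "effective threshold acceptable: construct a single logic gate")
    },
    single_gate = {
      if (isFALSE(state$correct))
        adv("recalibrate_gate_threshold",
            "incorrect single-gate computation indicates this gate's threshold species is an outlier: repeat signal restoration to calibrate this particular threshold")
      else adv("proceed_gate_calibration",
               "single gate computes correctly: run gate calibration experiments")
    },
    gate_calibration = {
      goa <- state$gamma_over_alpha
      if (is.null(goa)) stop("gate_calibration stage needs gamma_over_alpha")
      if (goa < 0.8)
        adv("adjust_all_gates",
            sprintf("gate-to-signal ratio %.2f < 0.8: adjust all nominal gate concentrations (multiply by %.2f)", goa, 0.8 / goa))
      else adv("proceed_two_layer",
               "gate-to-signal ratio acceptable: construct a two-layer circuit")
    },
    two_layer = {
      if (!is.null(state$outlier) && !isFALSE(state$outlier))
        adv("recalibrate_outlier_gate",
            "unequal ON signals on the downstream gate's input wires indicate an outlier gate: measure its own gamma/alpha and adjust its nominal concentration")
      else if (isFALSE(state$separation_ok)) {
        if (isTRUE(state$on_faster))
          adv("increase_output_threshold",
              "poor ON/OFF separation with all ON trajectories faster than OFF: increase the nominal threshold in the logic gate producing the circuit output by delta * alpha/beta")
        else
          adv("recalibrate",
              "poor separation without fast ON trajectories cannot be tuned away: recalibrate thresholds and gates")
      } else adv("proceed_larger_circuit",
                 "two-layer circuit behaves: continue to a larger circuit")
    },
    larger_circuit = {
      if (isFALSE(state$correct))
        adv("identify_worst_outlier",
            "incorrect larger-circuit computation: identify the outlier gate from the input cases with the worst ON/OFF separation and repeat its calibration")
      else adv("done", "circuit construction complete")
    },
    stop("unknown stage: ", stage))
}

#' @export
print.seesaw_advice <- function(x, ...) {
  cat(sprintf("[%s] %s\n  %s\n", x$stage, x$action, x$message))
  invisible(x)
}
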