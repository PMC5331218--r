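#' Rate constants of the seesaw reaction model
#'
#' @param k_f Fast bimolecular rate for thresholding, in M^-1 s^-1.
#' @param k_s Slow bimolecular rate for seesaw toehold exchange, M^-1 s^-1.
#' @param k_l Leak bimolecular rate, M^-1 s^-1.
#' @param k_rf,k_rs Fast/slow unimolecular rates (s^-1) of the two-step
#'   toehold-binding treatment; carried for completeness but unused by the
#'   single-step reaction scheme implemented here.
#' @param k_rep Reporting bimolecular rate; defaults to `k_f`.
#' @return A `rate_config` list.
#' @export
rate_config <- function(k_f = 2e6, k_s = 5e4, k_l = 10,
                        k_rf = 26, k_rs = 1.3, k_rep = k_f) {
  stopifnot(k_f > 0, k_s > 0, k_l > 0, k_rf > 0, k_rs > 0, k_rep > 0,
            k_f > k_s)
  structure(list(k_f = k_f, k_s = k_s, k_l = k_l, k_rf = k_rf, k_rs = k_rs,
                 k_rep = k_rep), class = "rate_config")
}

new_crn <- function(species, reactions, composition, std_conc_nM,
                    circuit = NULL) {
  structure(list(species = species, reactions = reactions,
                 composition = composition, std_conc_nM = std_conc_nM,
                 circuit = circuit),
            class = "seesaw_crn")
}

#' @export
print.seesaw_crn <- function(x, ...) {
  cat(sprintf("seesaw_crn: %d species, %d reactions (%s), 1x = %g nM\n",
              nrow(x$species), nrow(x$reactions),
              paste(sprintf("%s=%d", names(table(x$reactions$type)),
                            as.integer(table(x$reactions$type))),
                    collapse = ", "),
              x$std_conc_nM))
  invisible(x)
}

#' Build the mass-action reaction network of a compiled circuit
#' (purified model)
#'
#' Generates, for every seesaw node, the reversible toehold-exchange
#' (seesawing) reactions between each incoming signal and each output-side
#' strand (gate outputs and fuel) at `k_s` in both directions; the
#' irreversible thresholding reaction consuming each incoming signal at
#' `k_f`; irreversible reporter displacement at `k_rep`; and the leak set:
#' blunt-end exchange in which any free output-side strand (fuel or
#' signal) displaces any other bound output strand at `k_l`, the slow
#' spurious-release pathway of the prior seesaw model.
#'
#' @param circuit A `seesaw_circuit`.
#' @param rates A [rate_config()].
#' @param inputs Optional input assignment for the original circuit (named
#'   0/1 vector or bitstring): ON rails are set to `input_on`, OFF rails to
#'   `input_off`. When `NULL`, every input rail starts at `input_on`.
#' @param excess_signal_frac Stoichiometry-error emulation: fraction of
#'   each amplifying/fanout gate:output released as free signal at t = 0
#'   (annealing excess of one strand). Default 0 (none).
#' @param binding Include the universal toehold-binding (occlusion)
#'   reactions, the fifth reaction type of the seesaw network model: every
#'   free signal strand reversibly occupies the exposed universal toeholds
#'   of the double-stranded species (association at `k_f` against the
#'   total toehold load, dissociation at the slow unimolecular rate
#'   `k_rs`). Because toehold exchange conserves the number of
#'   toehold-bearing complexes, the load is treated as a constant
#'   mean-field computed from the initial gate, threshold and reporter
#'   concentrations, which keeps the occlusion set linear in the number of
#'   strands.
#' @return A `seesaw_crn` with species (initial concentrations in relative
#'   x units), reactions and strand-moiety compositions.
#' @export
build_purified_crn <- function(circuit, rates = rate_config(), inputs = NULL,
                               excess_signal_frac = 0, binding = TRUE) {
  stopifnot(inherits(circuit, "seesaw_circuit"))
  comp <- circuit$composition
  init <- setNames(circuit$species$conc_x, circuit$species$id)
  role <- setNames(circuit$species$role, circuit$species$id)
  if (any(is.na(init)) || any(init < 0))
    stop("species without a valid concentration")

  if (!is.null(inputs)) {
    src <- circuit$dual_rail$source
    bits <- as_assignment(src, inputs)
    for (x in names(bits)) {
      on_rail <- circuit$dual_rail$rails[[x]][["on"]]
      off_rail <- circuit$dual_rail$rails[[x]][["off"]]
      init[circuit$input_species[[on_rail]]] <-
        if (bits[[x]] == 1) circuit$config$input_on else circuit$config$input_off
      init[circuit$input_species[[off_rail]]] <-
        if (bits[[x]] == 1) circuit$config$input_off else circuit$config$input_on
    }
  }

  species <- list()
  add_sp <- function(id, x, rl, cp) {
    if (!is.null(species[[id]])) return(invisible(NULL))
    species[[id]] <<- list(id = id, init_x = x, role = rl)
    comp[[id]] <<- cp
  }
  for (i in seq_len(nrow(circuit$species))) {
    s <- circuit$species[i, ]
    add_sp(s$id, init[[s$id]], s$role, comp[[s$id]])
  }

  rxn <- list()
  add_rxn <- function(reactants, products, rate, type, rev = NA_integer_) {
    rxn[[length(rxn) + 1]] <<- list(reactants = reactants, products = products,
                                    rate = rate, type = type, rev = rev)
    length(rxn)
  }

  nodes <- circuit$nodes
  wires <- circuit$wires
  sink_of <- function(node) {
    # fuel sink node allocated for `node`, if any
    fs <- nodes$id[nodes$kind == "fuel_sink" &
                     nodes$label == sprintf("fuel_%d", node)]
    if (length(fs)) fs else NULL
  }

  for (i in which(nodes$kind %in% c("fanout", "integrating", "amplifying"))) {
    nd <- nodes[i, ]
    in_wires <- wires[wires$to == nd$id, ]
    out_wires <- wires[wires$from == nd$id, ]
    outs <- out_wires$to
    fs <- sink_of(nd$id)
    out_targets <- c(outs, fs) # fuel behaves as one more output-side strand

    base_m <- sprintf("base_%d", nd$id)
    for (k in out_targets) {
      wid <- sprintf("w_%d_%d", nd$id, k)
      gid <- sprintf("g_%d_%d", nd$id, k)
      add_sp(wid, 0, if (identical(k, fs)) "fuel" else "signal",
             sprintf("s_%d_%d", nd$id, k))
      add_sp(gid, 0, "gate_output", c(base_m, sprintf("s_%d_%d", nd$id, k)))
    }
    for (j in seq_len(nrow(in_wires))) {
      win <- in_wires$species[j]
      from <- in_wires$from[j]
      bid <- sprintf("b_%d_%d", from, nd$id)
      add_sp(win, 0, "signal", sprintf("s_%d_%d", from, nd$id))
      add_sp(bid, 0, "bound_gate",
             c(base_m, sprintf("s_%d_%d", from, nd$id)))
      for (k in out_targets) {
        wid <- sprintf("w_%d_%d", nd$id, k)
        gid <- sprintf("g_%d_%d", nd$id, k)
        f <- add_rxn(c(win, gid), c(bid, wid), rates$k_s, "seesawing")
        b <- add_rxn(c(wid, bid), c(gid, win), rates$k_s, "seesawing")
        rxn[[f]]$rev <- b; rxn[[b]]$rev <- f
      }
      thid <- sprintf("th_%d_%d", from, nd$id)
      if (thid %in% names(species)) {
        wst <- sprintf("thw_%d_%d", from, nd$id)
        add_sp(wst, 0, "waste",
               c(comp[[thid]], sprintf("s_%d_%d", from, nd$id)))
        add_rxn(c(win, thid), wst, rates$k_f, "thresholding")
      }
    }
    # leak: free output-side strand displaces any other bound output strand
    if (length(out_targets) >= 2) {
      for (k1 in out_targets) for (k2 in out_targets) {
        if (identical(k1, k2)) next
        add_rxn(c(sprintf("w_%d_%d", nd$id, k1), sprintf("g_%d_%d", nd$id, k2)),
                c(sprintf("g_%d_%d", nd$id, k1), sprintf("w_%d_%d", nd$id, k2)),
                rates$k_l, "leak")
      }
    }
  }

  for (i in which(nodes$kind == "reporter")) {
    r <- nodes$id[i]
    in_w <- wires[wires$to == r, ]
    win <- in_w$species[1]
    repid <- sprintf("rep_%d", r)
    fl <- sprintf("fluor_%d", r); q <- sprintf("q_%d", r)
    add_sp(win, 0, "signal", sprintf("s_%d_%d", in_w$from[1], r))
    add_sp(fl, 0, "fluorophore",
           c(sprintf("repb_%d", r), sprintf("s_%d_%d", in_w$from[1], r)))
    add_sp(q, 0, "quencher_strand", sprintf("rept_%d", r))
    add_rxn(c(win, repid), c(fl, q), rates$k_rep, "reporting")
  }

  if (binding) {
    # mean-field universal toehold occlusion: strand <-> occluded strand.
    # Only gate:output complexes enter the load: toehold exchange converts
    # them 1:1 into bound gates (also toehold-exposing), so their total is
    # conserved and the field is genuinely constant, whereas thresholds
    # and reporters are consumed during computation.
    load_x <- sum(vapply(species, function(s)
      if (s$role == "gate_output") s$init_x else 0, numeric(1)))
    k_on <- rates$k_f * load_x * circuit$config$std_conc_nM * 1e-9 # s^-1
    strand_ids <- names(species)[vapply(species, function(s)
      s$role %in% c("input", "signal", "fuel"), logical(1))]
    for (s in strand_ids) {
      oid <- paste0("occ_", s)
      add_sp(oid, 0, "occluded", comp[[s]])
      add_rxn(s, oid, k_on, "binding_on")
      add_rxn(oid, s, rates$k_rs, "binding_off")
    }
  }

  sp <- do.call(rbind, lapply(species, function(s)
    data.frame(id = s$id, init_x = s$init_x, role = s$role)))
  rownames(sp) <- NULL

  if (excess_signal_frac > 0) {
    for (i in which(nodes$kind %in% c("fanout", "amplifying"))) {
      nd <- nodes[i, ]
      for (k in wires$to[wires$from == nd$id]) {
        gid <- sprintf("g_%d_%d", nd$id, k)
        wid <- sprintf("w_%d_%d", nd$id, k)
        amt <- excess_signal_frac * sp$init_x[sp$id == gid]
        sp$init_x[sp$id == wid] <- sp$init_x[sp$id == wid] + amt
      }
    }
  }

  reactions <- data.frame(
    r1 = vapply(rxn, function(x) x$reactants[1], character(1)),
    r2 = vapply(rxn, function(x) if (length(x$reactants) > 1)
      x$reactants[2] else NA_character_, character(1)),
    p1 = vapply(rxn, function(x) x$products[1], character(1)),
    p2 = vapply(rxn, function(x) if (length(x$products) > 1)
      x$products[2] else NA_character_, character(1)),
    rate = vapply(rxn, function(x) x$rate, numeric(1)),
    type = vapply(rxn, function(x) x$type, character(1)),
    rev = vapply(rxn, function(x) x$rev, integer(1)))

  net <- new_crn(sp, reactions, comp, circuit$config$std_conc_nM, circuit)
  net$rates <- rates
  net
}

#' Re-assign the input strands of a built network
#'
#' Sets the initial concentrations of the input rail strands for a new
#' input assignment without rebuilding (or re-expanding) the network; for
#' an unpurified network the new nominal concentration is redistributed
#' over the input's error-population variants.
#'
#' @param net A `seesaw_crn` carrying its circuit.
#' @param inputs Input assignment (bitstring or named 0/1 vector over the
#'   original circuit inputs).
#' @return The network with updated initial concentrations.
#' @export
set_network_inputs <- function(net, inputs) {
  circuit <- net$circuit
  stopifnot(!is.null(circuit))
  src <- circuit$dual_rail$source
  bits <- as_assignment(src, inputs)
  rail_x <- numeric()
  for (x in names(bits)) {
    on_rail <- circuit$dual_rail$rails[[x]][["on"]]
    off_rail <- circuit$dual_rail$rails[[x]][["off"]]
    rail_x[circuit$input_species[[on_rail]]] <-
      if (bits[[x]] == 1) circuit$config$input_on else circuit$config$input_off
    rail_x[circuit$input_species[[off_rail]]] <-
      if (bits[[x]] == 1) circuit$config$input_off else circuit$config$input_on
  }
  ecfg <- net$error_config
  for (id in names(rail_x)) {
    if (is.null(ecfg)) {
      net$species$init_x[net$species$id == id] <- rail_x[[id]]
    } else {
      pop <- partition_species(net$composition[[id]], ecfg)
      for (j in seq_len(nrow(pop))) {
        vid <- variant_id(id, pop$variant[j])
        hit <- net$species$id == vid
        if (any(hit)) net$species$init_x[hit] <- rail_x[[id]] * pop$fraction[j]
      }
    }
  }
  net
}

#' Integrate a reaction network as mass-action ODEs
#'
#' Deterministic simulation in nM units with a stiff-capable integrator
#' (`lsoda` with an analytic Jacobian for small networks, sparse `lsodes`
#' for expanded synthesis-error networks).
#'
#' @param net A `seesaw_crn`.
#' @param t_end_h End time in hours.
#' @param n_out Number of output time points (evenly spaced from 0).
#' @param rtol,atol Relative / absolute (nM) solver tolerances.
#' @param method `"lsoda"`, `"lsodes"` or `NULL` to pick by network size.
#' @return A `crn_trajectories` data frame: `time` (hours) plus one column
#'   per species (nM).
#' @export
simulate_crn <- function(net, t_end_h = 24, n_out = 241,
                         rtol = 1e-8, atol = 1e-10, method = NULL) {
  sp <- net$species
  n <- nrow(sp)
  idx <- setNames(seq_len(n), sp$id)
  rx <- net$reactions
  m <- nrow(rx)
  i1 <- idx[rx$r1]
  i2 <- ifelse(is.na(rx$r2), NA_integer_, idx[rx$r2])
  bi <- !is.na(i2)
  # convert bimolecular rates from per-M to per-nM
  k <- rx$rate * ifelse(bi, 1e-9, 1)

  trip_i <- c(i1, i2[bi],
              idx[rx$p1], idx[rx$p2[!is.na(rx$p2)]])
  trip_j <- c(seq_len(m), which(bi),
              seq_len(m), which(!is.na(rx$p2)))
  trip_x <- c(rep(-1, m), rep(-1, sum(bi)),
              rep(1, m), rep(1, sum(!is.na(rx$p2))))
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, m))

  i2f <- ifelse(bi, i2, 1L) # dummy index; multiplied by 1 below
  deriv <- function(t, y, parms) {
    y2 <- ifelse(bi, y[i2f], 1)
    v <- k * y[i1] * y2
    list(as.vector(S %*% v))
  }
  jac <- function(t, y, parms) {
    di <- c(seq_len(m), which(bi))
    dj <- c(i1, i2[bi])
    dx <- c(k * ifelse(bi, y[i2f], 1), (k * y[i1])[bi])
    D <- Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(m, n))
    as.matrix(S %*% D)
  }

  y0 <- sp$init_x * net$std_conc_nM
  names(y0) <- sp$id
  times <- seq(0, t_end_h * 3600, length.out = n_out)
  if (is.null(method)) method <- if (n <= 300) "lsoda" else "lsodes"
  out <- if (method == "lsoda") {
    deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                 jacfunc = jac, jactype = "fullusr",
                 rtol = rtol, atol = atol, maxsteps = 1e5)
  } else {
    deSolve::ode(y0, times, deriv, NULL, method = "lsodes",
                 rtol = rtol, atol = atol, maxsteps = 1e5)
  }
  if (attr(out, "istate")[1] < 0) stop("ODE solver failed; istate = ",
                                       attr(out, "istate")[1])
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df$time <- df$time / 3600
  structure(df, class = c("crn_trajectories", "data.frame"), net = net)
}

#' Reporter completion trajectories of a circuit simulation
#'
#' Converts triggered-fluorophore concentrations into normalized completion
#' (fluorophore / standard concentration, the expected full-ON signal
#' level), one column per dual-rail output rail.
#'
#' @param net The simulated `seesaw_crn` (must carry its circuit).
#' @param traj Output of [simulate_crn()].
#' @return A `seesaw_traj` data frame: `time` (hours) plus one completion
#'   column per output rail.
#' @export
reporter_completion <- function(net, traj) {
  circuit <- net$circuit
  stopifnot(!is.null(circuit))
  rails <- names(circuit$reporter_species)
  out <- data.frame(time = traj$time)
  for (rail in rails) {
    rnode <- sub("^rep_", "", circuit$reporter_species[[rail]])
    fl <- paste0("fluor_", rnode)
    out[[rail]] <- traj[[fl]] / net$std_conc_nM
  }
  structure(out, class = c("seesaw_traj", "data.frame"))
}

#' Expected dual-rail output states for one input assignment
#'
#' @param circuit A compiled `seesaw_circuit`.
#' @param inputs Assignment for the original logic circuit.
#' @return Named 0/1 vector over output rail names (`<output>__1`,
#'   `<output>__0`).
#' @export
expected_rail_states <- function(circuit, inputs) {
  src <- circuit$dual_rail$source
  vals <- evaluate_circuit(src, inputs)
  unlist(lapply(names(vals), function(o) {
    setNames(c(vals[[o]], 1L - vals[[o]]), paste0(o, c("__1", "__0")))
  }))
}

#' Simulate a compiled circuit end to end
#'
#' Builds the purified CRN (expanding it with the synthesis-error
#' populations for the unpurified model), integrates it, and returns the
#' output-rail completion trajectories with the expected rail states
#' attached.
#'
#' @param circuit A `seesaw_circuit`.
#' @param inputs Input assignment (bitstring over the original inputs).
#' @param model `"purified"` or `"unpurified"`.
#' @param t_end_h Simulated duration in hours.
#' @param rates A [rate_config()].
#' @param error_config An [error_model_config()] (unpurified model only).
#' @param ... Passed to [simulate_crn()].
#' @return A `seesaw_traj` with attribute `expected`.
#' @export
simulate_circuit <- function(circuit, inputs,
                             model = c("purified", "unpurified"),
                             t_end_h = 24, rates = rate_config(),
                             error_config = error_model_config(), ...) {
  model <- match.arg(model)
  net <- build_purified_crn(circuit, rates, inputs)
  if (model == "unpurified") net <- expand_crn(net, error_config)
  traj <- simulate_crn(net, t_end_h = t_end_h, ...)
  out <- reporter_completion(net, traj)
  attr(out, "expected") <- expected_rail_states(circuit, inputs)
  out
}

#' Normalize trajectories against OFF/ON references
#'
#' Applies the fluorescence normalization rule: the first data point of the
#' OFF reference maps to 0 and the mean of the last five data points of the
#' ON reference maps to 1; the same affine map is applied to every
#' trajectory.
#'
#' @param traj A `seesaw_traj` (time column plus trajectory columns).
#' @param off_ref,on_ref Column names of the OFF and ON reference
#'   trajectories.
#' @return The normalized `seesaw_traj`.
#' @export
normalize_trajectories <- function(traj, off_ref, on_ref) {
  stopifnot(off_ref %in% names(traj), on_ref %in% names(traj),
            nrow(traj) >= 5)
  lo <- traj[[off_ref]][1]
  hi <- mean(tail(traj[[on_ref]], 5))
  if (abs(hi - lo) < .Machine$double.eps * 100)
    stop("degenerate references: ON and OFF levels coincide")
  cols <- setdiff(names(traj), "time")
  for (cl in cols) traj[[cl]] <- (traj[[cl]] - lo) / (hi - lo)
  attr(traj, "normalized") <- TRUE
  traj
}

#' Simulate a circuit over every input combination
#'
#' Builds the network once (expanding it once for the unpurified model),
#' re-assigns the inputs for each of the `2^n` assignments, simulates a
#' fixed-length record, normalizes each run against its own ON/OFF
#' references, and reports the completion time of the slowest expected-ON
#' rail together with the band-based correctness call.
#'
#' @param circuit A compiled `seesaw_circuit`.
#' @param model `"purified"` or `"unpurified"`.
#' @param record_h Simulated record length in hours.
#' @param read_time_h Read time for the correctness call (defaults to the
#'   end of the record).
#' @param rates A [rate_config()].
#' @param error_config An [error_model_config()] (unpurified model).
#' @param level Completion level for the crossing time.
#' @return Data frame with one row per input: `input`, `completion_h`
#'   (normalized crossing of `level`), `correct`.
#' @export
simulate_all_inputs <- function(circuit, model = c("purified", "unpurified"),
                                record_h = 36, read_time_h = NULL,
                                rates = rate_config(),
                                error_config = error_model_config(),
                                level = 0.7) {
  model <- match.arg(model)
  net0 <- build_purified_crn(circuit, rates)
  if (model == "unpurified") net0 <- expand_crn(net0, error_config)
  n <- length(circuit$dual_rail$source$inputs)
  rows <- lapply((2^n - 1):0, function(v) {
    bits <- paste(as.integer(intToBits(v))[n:1], collapse = "")
    net <- set_network_inputs(net0, bits)
    comp <- reporter_completion(net, simulate_crn(net, t_end_h = record_h))
    attr(comp, "expected") <- expected_rail_states(circuit, bits)
    nrm <- normalize_by_expectation(comp)
    data.frame(input = bits,
               completion_h = completion_time(nrm, level = level),
               correct = logic_outcome(nrm, read_time_h = read_time_h)$correct)
  })
  do.call(rbind, rows)
}

#' Normalize completion trajectories against their own ON/OFF references
#'
#' Applies the standard fluorescence normalization to a simulated
#' trajectory set using its expected rail states: the OFF reference is an
#' expected-OFF rail's first point, the ON reference is the expected-ON
#' rail with the largest final signal (mean of the last five points maps
#' to 1). This is how every reported trajectory is scaled, and it matters
#' for the unpurified model, whose absolute ON levels sit well below the
#' standard concentration because part of every population is defective.
#'
#' @param traj A `seesaw_traj` carrying an `expected` attribute.
#' @return The normalized trajectories (expectations preserved).
#' @export
normalize_by_expectation <- function(traj) {
  expected <- attr(traj, "expected")
  if (is.null(expected)) stop("trajectories carry no expected rail states")
  on_rails <- names(expected)[expected == 1]
  off_rails <- names(expected)[expected == 0]
  if (!length(on_rails) || !length(off_rails))
    stop("need at least one expected-ON and one expected-OFF rail")
  on_ref <- on_rails[which.max(vapply(on_rails, function(r)
    mean(tail(traj[[r]], 5)), numeric(1)))]
  out <- normalize_trajectories(traj, off_ref = off_rails[1], on_ref = on_ref)
  attr(out, "expected") <- expected
  out
}

traj_at <- function(traj, col, t) {
  approx(traj$time, traj[[col]], xout = t, rule = 2)$y
}

#' Classify a simulated/measured computation as correct or not
#'
#' Correct iff every expected-ON rail is at or above `on_floor` and every
#' expected-OFF rail at or below `off_ceiling` at the read time.
#'
#' @param traj A `seesaw_traj` of normalized completions.
#' @param expected Named 0/1 vector over rail columns.
#' @param on_floor,off_ceiling ON/OFF separation bounds (ideal lower-bound
#'   separation 0.7 / 0.3).
#' @param read_time_h Read time in hours (defaults to the last time point).
#' @return List with `correct` (logical) and the per-rail values.
#' @export
logic_outcome <- function(traj, expected = attr(traj, "expected"),
                          on_floor = 0.7, off_ceiling = 0.3,
                          read_time_h = NULL) {
  if (is.null(expected)) stop("no expected rail states supplied")
  missing <- setdiff(names(expected), names(traj))
  if (length(missing)) stop("missing rail(s): ", paste(missing, collapse = ", "))
  if (is.null(read_time_h)) read_time_h <- max(traj$time)
  vals <- vapply(names(expected), function(r) traj_at(traj, r, read_time_h),
                 numeric(1))
  ok <- all(vals[expected == 1] >= on_floor) &&
    all(vals[expected == 0] <= off_ceiling)
  list(correct = ok, values = vals, read_time_h = read_time_h)
}

#' Completion time of the slowest expected-ON rail
#'
#' First time at which the slowest of the given rails crosses `level`
#' (linear interpolation between output points); `NA` if any rail never
#' crosses.
#'
#' @param traj A `seesaw_traj`.
#' @param rails Rail columns to consider (default: rails with expected
#'   state 1, if the trajectory carries expectations; otherwise all).
#' @param level Completion level, default 0.7.
#' @return Time in hours, or `NA_real_` if not reached.
#' @export
completion_time <- function(traj, rails = NULL, level = 0.7) {
  if (is.null(rails)) {
    expected <- attr(traj, "expected")
    rails <- if (!is.null(expected)) names(expected)[expected == 1] else
      setdiff(names(traj), "time")
  }
  if (!length(rails)) return(NA_real_)
  crossing <- function(col) {
    y <- traj[[col]]
    if (y[1] >= level) return(0)
    ab <- which(y >= level)
    if (!length(ab)) return(NA_real_)
    i <- ab[1]
    t0 <- traj$time[i - 1]; t1 <- traj$time[i]
    t0 + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t1 - t0)
  }
  ts <- vapply(rails, crossing, numeric(1))
  if (anyNA(ts)) NA_real_ else max(ts)
}
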