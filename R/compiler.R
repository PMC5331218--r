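#' Compiler configuration
#'
#' Default relative concentrations (in units of the standard concentration
#' 1x) and structural choices used when compiling a dual-rail circuit into
#' a seesaw DNA circuit. The published diagrams show these values only as
#' red numbers next to species, so all of them are configurable here rather
#' than constants.
#'
#' @param std_conc_nM Standard concentration 1x in nM (100 in the
#'   experiments; 50 is the compiler-recommended value for simulating
#'   large purified circuits).
#' @param input_on,input_off Relative concentration of an input rail strand
#'   representing logic ON / OFF.
#' @param gate_output Relative concentration of each amplifying/fanout
#'   gate:output complex (one per outgoing wire); integrating gate:output
#'   complexes get `fan_in * gate_output`.
#' @param fuel_factor Fuel is supplied at `fuel_factor * total gate:output`
#'   of its node, so catalytic turnover can complete for every output.
#' @param reporter Relative concentration of each reporter complex.
#' @param fanout_threshold Ideal threshold on every input fan-out node,
#'   cleaning up the OFF rail (which is present at `input_off`).
#' @param beta_over_alpha Threshold-to-signal effective concentration ratio
#'   assumed when converting ideal thresholds to nominal ones (1 for
#'   purified molecules).
#' @return A `compiler_config` list.
#' @export
compiler_config <- function(std_conc_nM = 100,
                            input_on = 1, input_off = 0.1,
                            gate_output = 1, fuel_factor = 2,
                            reporter = 1.5, fanout_threshold = 0.2,
                            beta_over_alpha = 1) {
  stopifnot(std_conc_nM > 0, input_on > 0, input_off >= 0, gate_output > 0,
            fuel_factor > 0, reporter > 0, fanout_threshold > 0,
            beta_over_alpha > 0)
  structure(list(std_conc_nM = std_conc_nM, input_on = input_on,
                 input_off = input_off, gate_output = gate_output,
                 fuel_factor = fuel_factor, reporter = reporter,
                 fanout_threshold = fanout_threshold,
                 beta_over_alpha = beta_over_alpha),
            class = "compiler_config")
}

# Ideal (beta/alpha = 1) threshold for an n-input seesaw logic gate,
# from the OFF = [0, 0.2] / ON = [0.8, 1] band arithmetic of the
# integrating sum: OR must reject an all-OFF sum (<= 0.2 n) and pass any
# single ON (>= 0.8); AND must reject any one-OFF sum (<= n - 0.8) and
# pass the all-ON sum (>= 0.8 n). OR uses the band midpoint (0.6 for
# n = 2), AND the inclusive lower bound (1.2 for n = 2).
ideal_threshold <- function(op, n) {
  switch(op,
         OR = (0.2 * n + 0.8) / 2,
         AND = n - 0.8,
         stop("thresholds exist only for AND/OR seesaw gates"))
}

new_seesaw_circuit <- function(nodes, wires, species, composition, dr, config) {
  structure(list(nodes = nodes, wires = wires, species = species,
                 composition = composition, dual_rail = dr, config = config),
            class = "seesaw_circuit")
}

empty_seesaw_circuit <- function(config = compiler_config()) {
  new_seesaw_circuit(
    nodes = data.frame(id = integer(), kind = character(), label = character(),
                       op = character(), fan_in_n = integer()),
    wires = data.frame(from = integer(), to = integer(), species = character(),
                       role = character()),
    species = data.frame(id = character(), role = character(), node = integer(),
                         conc_x = numeric()),
    composition = list(), dr = NULL, config = config)
}

#' Compile a dual-rail circuit into a seesaw DNA circuit
#'
#' Applies the seesaw construction: every dual-rail AND/OR gate becomes a
#' pair of integrating and amplifying seesaw nodes (one gate:output complex
#' on the integrating node, and a threshold, a fuel strand and one
#' gate:output complex per outgoing wire on the amplifying node); every
#' dual-rail input rail gets an input fan-out node (threshold, fuel, one
#' gate:output per consumer) even when it has a single consumer; every
#' dual-rail circuit output gets a reporter. The AND/OR distinction is
#' realized purely through the amplifying node's threshold concentration.
#'
#' Node indices are assigned deterministically: input sources and fan-out
#' nodes first (in input order, ON rail before OFF rail), then one
#' integrating and one amplifying node per gate in topological order, then
#' reporters, then virtual fuel sinks.
#'
#' @param dr A `dual_rail_circuit` (or a `logic_circuit`, which is
#'   dual-rail transformed first).
#' @param config A [compiler_config()].
#' @return A `seesaw_circuit` with node, wire and initial-species tables.
#' @export
compile_seesaw <- function(dr, config = compiler_config()) {
  if (inherits(dr, "logic_circuit")) dr <- to_dual_rail(dr)
  stopifnot(inherits(dr, "dual_rail_circuit"))

  nid <- 0L
  nodes <- list()
  add_node <- function(kind, label, op = NA_character_, fan_in_n = NA_integer_) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, kind = kind, label = label,
                                op = op, fan_in_n = fan_in_n)
    nid
  }

  # input rails: a virtual source node plus a fan-out node each
  input_rails <- unlist(lapply(dr$inputs, function(x) unname(dr$rails[[x]])))
  source_of <- fanout_of <- setNames(integer(length(input_rails)), input_rails)
  for (rail in input_rails) {
    source_of[rail] <- add_node("source", rail)
    fanout_of[rail] <- add_node("fanout", rail)
  }

  producer <- setNames(fanout_of, input_rails) # rail net -> producing node
  int_of <- amp_of <- setNames(integer(length(dr$gates)),
                               vapply(dr$gates, `[[`, character(1), "name"))
  for (g in dr$gates) {
    int_of[g$name] <- add_node("integrating", g$name, g$op, length(g$fan_in))
    amp_of[g$name] <- add_node("amplifying", g$name, g$op, length(g$fan_in))
    producer[g$name] <- amp_of[g$name]
  }

  output_rails <- unlist(lapply(names(dr$outputs), function(o) {
    setNames(unname(dr$outputs[[o]]), paste0(o, c("__1", "__0")))
  }))
  if (length(output_rails) == 0 && length(dr$gates) == 0 &&
      length(input_rails) == 0) return(empty_seesaw_circuit(config))
  reporter_of <- setNames(integer(length(output_rails)), names(output_rails))
  for (i in seq_along(output_rails)) {
    reporter_of[i] <- add_node("reporter", names(output_rails)[i])
  }

  # consumers of each rail net: integrating nodes of gates using it, plus
  # reporters of outputs wired to it
  consumers <- lapply(setNames(nm = names(producer)), function(r) integer())
  for (g in dr$gates) {
    for (f in g$fan_in) consumers[[f]] <- c(consumers[[f]], int_of[[g$name]])
  }
  for (i in seq_along(output_rails)) {
    rail <- output_rails[[i]]
    consumers[[rail]] <- c(consumers[[rail]], reporter_of[[i]])
  }
  dead <- names(consumers)[vapply(consumers, length, integer(1)) == 0]
  if (length(dead)) {
    stop("rail(s) with zero consumers (unused net or unconnected output): ",
         paste(dead, collapse = ", "))
  }

  wires <- list()
  species <- list()
  composition <- list()
  add_wire <- function(from, to, role) {
    id <- sprintf("w_%d_%d", from, to)
    wires[[length(wires) + 1]] <<- data.frame(from = from, to = to,
                                              species = id, role = role)
    id
  }
  add_species <- function(id, role, node, conc_x, comp) {
    species[[length(species) + 1]] <<- data.frame(id = id, role = role,
                                                  node = node, conc_x = conc_x)
    composition[[id]] <<- comp
    id
  }
  signal_comp <- function(from, to) sprintf("s_%d_%d", from, to)

  boa <- config$beta_over_alpha

  add_amplifying_side <- function(node, in_node, threshold_x, outs) {
    # threshold on the single incoming wire, fuel, one gate:output per
    # outgoing wire
    add_species(sprintf("th_%d_%d", in_node, node), "threshold", node,
                threshold_x / boa,
                c(sprintf("thb_%d_%d", in_node, node), sprintf("tht_%d", node)))
    fsink <- add_node("fuel_sink", sprintf("fuel_%d", node))
    add_species(sprintf("w_%d_%d", node, fsink), "fuel", node,
                config$fuel_factor * length(outs) * config$gate_output,
                signal_comp(node, fsink))
    for (k in outs) {
      add_species(sprintf("g_%d_%d", node, k), "gate_output", node,
                  config$gate_output,
                  c(sprintf("base_%d", node), signal_comp(node, k)))
    }
  }

  # fan-out nodes
  for (rail in input_rails) {
    s <- source_of[[rail]]; fo <- fanout_of[[rail]]
    wid <- add_wire(s, fo, "input")
    add_species(wid, "input", fo, config$input_on, signal_comp(s, fo))
    cs <- consumers[[rail]]
    for (c in cs) add_wire(fo, c, "signal")
    add_amplifying_side(fo, s, config$fanout_threshold, cs)
  }

  # logic gates: integrating + amplifying node pair
  for (g in dr$gates) {
    m <- int_of[[g$name]]; a <- amp_of[[g$name]]
    # fan-in wires into the integrating node were already laid down by
    # the upstream producer's loop; here only the producer-side wires
    add_wire(m, a, "signal")
    add_species(sprintf("g_%d_%d", m, a), "gate_output", m,
                length(g$fan_in) * config$gate_output,
                c(sprintf("base_%d", m), signal_comp(m, a)))
    cs <- consumers[[g$name]]
    for (c in cs) add_wire(a, c, "signal")
    add_amplifying_side(a, m, ideal_threshold(g$op, length(g$fan_in)), cs)
  }

  # reporters
  for (i in seq_along(output_rails)) {
    r <- reporter_of[[i]]
    add_species(sprintf("rep_%d", r), "reporter", r, config$reporter,
                c(sprintf("repb_%d", r), sprintf("rept_%d", r)))
  }

  ssc <- new_seesaw_circuit(do.call(rbind, nodes), do.call(rbind, wires),
                            do.call(rbind, species), composition, dr, config)
  ssc$input_species <- setNames(
    sprintf("w_%d_%d", source_of, fanout_of), input_rails)
  ssc$reporter_species <- setNames(sprintf("rep_%d", reporter_of),
                                   names(output_rails))
  ssc$reporter_rail <- output_rails
  ssc
}

#' @export
print.seesaw_circuit <- function(x, ...) {
  cnt <- table(factor(x$species$role,
                      levels = c("input", "gate_output", "threshold", "fuel",
                                 "reporter")))
  cat(sprintf("seesaw_circuit: %d nodes, %d wires, %d initial DNA species, %d layers\n",
              sum(x$nodes$kind != "source" & x$nodes$kind != "fuel_sink"),
              nrow(x$wires), nrow(x$species), circuit_depth(x)))
  cat("  species by role: ",
      paste(sprintf("%s=%d", names(cnt), as.integer(cnt)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate the distinct initial DNA species of a compiled circuit
#'
#' @param circuit A `seesaw_circuit`.
#' @return Data frame of the initial species (id, role, owning node,
#'   relative concentration), in the deterministic compile order, with a
#'   `counts` attribute partitioning the total by role.
#' @export
enumerate_species <- function(circuit) {
  sp <- circuit$species
  attr(sp, "counts") <- c(table(sp$role), total = nrow(sp))
  sp
}

#' Layer count of a compiled seesaw circuit
#'
#' Longest input-to-reporter path, counting the fan-out layer, every
#' integrating and amplifying layer, and the reporter layer (the full
#' two-layer logic demonstration circuit has 6 seesaw layers).
#'
#' @param circuit A `seesaw_circuit`.
#' @return Integer layer count (0 for an empty circuit).
#' @export
circuit_depth <- function(circuit) {
  nodes <- circuit$nodes
  real <- nodes$kind %in% c("fanout", "integrating", "amplifying", "reporter")
  if (!any(real)) return(0L)
  depth <- setNames(rep(0L, nrow(nodes)), nodes$id)
  # nodes were created in topological order except sources/fuel sinks,
  # which carry no depth; iterate in id order
  for (id in sort(nodes$id)) {
    preds <- circuit$wires$from[circuit$wires$to == id]
    base <- if (length(preds)) max(depth[as.character(preds)]) else 0L
    own <- as.integer(nodes$kind[nodes$id == id] %in%
                        c("fanout", "integrating", "amplifying", "reporter"))
    depth[as.character(id)] <- base + own
  }
  max(depth)
}

# Remove one output's reporter (species, node and incoming wire); used to
# check that a reporter accounts for exactly one species and at most one
# layer of depth.
drop_reporter <- function(circuit, output_rail) {
  rep_sp <- circuit$reporter_species[[output_rail]]
  rnode <- circuit$species$node[circuit$species$id == rep_sp]
  circuit$species <- circuit$species[circuit$species$id != rep_sp, ]
  circuit$wires <- circuit$wires[circuit$wires$to != rnode, ]
  circuit$nodes <- circuit$nodes[circuit$nodes$id != rnode, ]
  circuit$reporter_species <- circuit$reporter_species[
    names(circuit$reporter_species) != output_rail]
  circuit
}

#' Assign or re-assign species concentrations
#'
#' Recomputes threshold concentrations from gate type and fan-in (dividing
#' ideal thresholds by the threshold-to-signal ratio beta/alpha when a
#' calibration state is supplied), applies the gate-concentration
#' adjustment when gamma/alpha < 0.8, and applies any per-species outlier
#' adjustments recorded in the calibration state.
#'
#' @param circuit A `seesaw_circuit`.
#' @param config A [compiler_config()]; defaults to the one the circuit was
#'   compiled with.
#' @param calibration Optional [calibration_state()].
#' @return The circuit with an updated species table.
#' @export
assign_concentrations <- function(circuit, config = NULL, calibration = NULL) {
  if (is.null(config)) config <- circuit$config
  boa <- if (!is.null(calibration)) calibration$beta_over_alpha else
    config$beta_over_alpha
  sp <- circuit$species
  nodes <- circuit$nodes
  for (i in which(sp$role == "threshold")) {
    nd <- nodes[nodes$id == sp$node[i], ]
    ideal <- if (nd$kind == "fanout") config$fanout_threshold else
      ideal_threshold(nd$op, nd$fan_in_n)
    sp$conc_x[i] <- ideal / boa
  }
  if (!is.null(calibration) && calibration$gamma_over_alpha < 0.8) {
    gi <- sp$role == "gate_output"
    sp$conc_x[gi] <- adjust_gate_nominals(sp$conc_x[gi],
                                          calibration$gamma_over_alpha)
  }
  if (!is.null(calibration) && length(calibration$outliers)) {
    for (id in names(calibration$outliers)) {
      j <- which(sp$id == id)
      if (!length(j)) stop("outlier species not in circuit: ", id)
      common <- if (sp$role[j] == "threshold") boa else
        calibration$gamma_over_alpha
      sp$conc_x[j] <- adjust_outlier(sp$conc_x[j], common,
                                     calibration$outliers[[id]])
    }
  }
  circuit$species <- sp
  circuit$config$beta_over_alpha <- boa
  circuit
}

#' Nominal concentrations used in the unpurified-circuit experiments
#'
#' Applies the study's final nominal concentration set for building seesaw
#' circuits from unpurified strands with beta/alpha = 1.4: thresholds of
#' 0.35x / 0.85x for two-input OR / AND gates and 0.4x / 1.6x for
#' three-input OR / AND gates, fan-out thresholds divided by beta/alpha,
#' and the output-tuning increase `delta * alpha/beta` added to the
#' threshold of every logic gate that directly drives a reporter.
#'
#' @param circuit A `seesaw_circuit`.
#' @param beta_over_alpha Threshold-to-signal ratio (1.4 measured for the
#'   unpurified molecules).
#' @param delta ON/OFF separation deficit used for output tuning; defaults
#'   to the midpoint of the measured 0.08--0.41 range. The upper end
#'   suppresses OFF leak hardest but raises the effective output threshold
#'   to the edge of the unpurified ON sum and stalls the circuit; the
#'   midpoint trades suppression against ON slowdown.
#' @return The circuit with the experimental species concentrations.
#' @export
experimental_concentrations <- function(circuit, beta_over_alpha = 1.4,
                                        delta = (0.08 + 0.41) / 2) {
  chosen <- list(OR = c(`2` = 0.35, `3` = 0.4), AND = c(`2` = 0.85, `3` = 1.6))
  sp <- circuit$species
  nodes <- circuit$nodes
  out_nodes <- nodes$id[nodes$kind == "reporter"]
  # amplifying nodes wired into a reporter belong to output-layer gates
  output_amps <- unique(circuit$wires$from[circuit$wires$to %in% out_nodes])
  for (i in which(sp$role == "threshold")) {
    nd <- nodes[nodes$id == sp$node[i], ]
    if (nd$kind == "fanout") {
      sp$conc_x[i] <- circuit$config$fanout_threshold / beta_over_alpha
    } else {
      pick <- chosen[[nd$op]][as.character(nd$fan_in_n)]
      sp$conc_x[i] <- if (!is.na(pick)) unname(pick) else
        ideal_threshold(nd$op, nd$fan_in_n) / beta_over_alpha
      if (nd$id %in% output_amps) {
        sp$conc_x[i] <- tune_output_threshold(
          sp$conc_x[i], delta, calibration_state(beta_over_alpha = beta_over_alpha))
      }
    }
  }
  circuit$species <- sp
  circuit$config$beta_over_alpha <- beta_over_alpha
  circuit
}

#' Write the species table as CSV
#'
#' Columns: id, role, node, domains (strand moieties), relative
#' concentration and absolute concentration in nM given the standard
#' concentration.
#'
#' @param circuit A `seesaw_circuit`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_species_csv <- function(circuit, path) {
  sp <- enumerate_species(circuit)
  sp$domains <- vapply(sp$id, function(id)
    paste(circuit$composition[[id]], collapse = ";"), character(1))
  sp$conc_nM <- sp$conc_x * circuit$config$std_conc_nM
  write.csv(sp, path, row.names = FALSE, quote = FALSE)
  invisible(sp)
}
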