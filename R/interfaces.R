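#' Random feedforward logic circuit
#'
#' Property-test fixture generator: gates draw their operation and fan-in
#' at random from earlier-declared nets, so the result is always a valid
#' feedforward circuit; deterministic for a given seed.
#'
#' @param n_inputs Number of inputs (>= 1).
#' @param n_gates Number of gates (0 gives a passthrough circuit).
#' @param fan_in Candidate fan-in values for multi-input gates.
#' @param seed Integer seed.
#' @param ops Candidate gate operations.
#' @return A `logic_circuit` with one output per terminal gate (or a
#'   passthrough output for a gateless circuit).
#' @export
random_circuit <- function(n_inputs, n_gates, fan_in = 2:3, seed = 1,
                           ops = c("AND", "OR", "NOT", "NAND", "NOR")) {
  stopifnot(n_inputs >= 1, n_gates >= 0)
  withr::with_seed(seed, {
    inputs <- paste0("x", seq_len(n_inputs))
    pool <- inputs
    gates <- list()
    for (i in seq_len(n_gates)) {
      op <- sample(ops, 1)
      k <- if (op == "NOT") 1 else min(sample(rep(fan_in, 2), 1), length(pool))
      if (op != "NOT" && k < 2) op <- "NOT" # tiny pool: degrade gracefully
      nm <- paste0("g", i)
      gates[[i]] <- list(name = nm, op = op,
                         fan_in = sample(pool, if (op == "NOT") 1 else k))
      pool <- c(pool, nm)
    }
    used <- unique(unlist(lapply(gates, `[[`, "fan_in")))
    terminal <- setdiff(vapply(gates, `[[`, character(1), "name"), used)
    outputs <- if (length(gates) == 0) c(y1 = inputs[1]) else
      setNames(terminal, paste0("y", seq_along(terminal)))
    structure(list(inputs = inputs, gates = gates, outputs = outputs),
              class = "logic_circuit")
  })
}

#' Logistic parameters through two points
#'
#' Solves for the midpoint and time-scale of the logistic
#' `y0 + (y1 - y0) / (1 + exp(-(t - t50)/tau))` passing exactly through
#' `(t1, v1)` and `(t2, v2)`.
#'
#' @param t1,v1,t2,v2 The two points (values strictly between y0 and y1).
#' @param y0,y1 Lower/upper asymptotes.
#' @return `list(t50 = , tau = )`.
#' @export
logistic_through <- function(t1, v1, t2, v2, y0 = 0, y1 = 1) {
  logit <- function(v) {
    p <- (v - y0) / (y1 - y0)
    stopifnot(p > 0, p < 1)
    log(p / (1 - p))
  }
  l1 <- logit(v1); l2 <- logit(v2)
  tau <- (t2 - t1) / (l2 - l1)
  list(t50 = t1 - tau * l1, tau = tau)
}

#' Synthetic normalized-fluorescence trajectories
#'
#' Generates sigmoidal trajectories emulating normalized reporter
#' kinetics, for exercising the calibration toolkit without wet-lab data.
#' At zero noise each trajectory passes exactly through the values implied
#' by its logistic parameters.
#'
#' @param spec List of per-trajectory specs: `list(name =, y0 =, y1 =,
#'   t50 =, tau =)`.
#' @param times Time grid (hours).
#' @param noise Gaussian noise s.d. added to every point (0 = exact).
#' @param seed Seed for the noise.
#' @return A `seesaw_traj` data frame.
#' @export
synthetic_trajectories <- function(spec, times = seq(0, 24, by = 0.1),
                                   noise = 0, seed = 1) {
  out <- data.frame(time = times)
  withr::with_seed(seed, {
    for (s in spec) {
      y <- s$y0 + (s$y1 - s$y0) / (1 + exp(-(times - s$t50) / s$tau))
      if (noise > 0) y <- y + rnorm(length(y), 0, noise)
      out[[s$name]] <- y
    }
  })
  structure(out, class = c("seesaw_traj", "data.frame"))
}

#' Read/write trajectories as CSV
#'
#' First column `time` (hours), one column per trajectory.
#' @param traj A `seesaw_traj`.
#' @param path CSV path.
#' @export
write_trajectories_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  df <- read.csv(path)
  names(df)[1] <- "time"
  structure(df, class = c("seesaw_traj", "data.frame"))
}

#' Full run configuration
#'
#' Aggregates every tunable constant of the pipeline in one object that
#' can be written to / read from a YAML config file, so each model
#' constant lives in exactly one namespace with its published default.
#'
#' @param std_conc_nM Standard concentration 1x (nM).
#' @param rates A [rate_config()].
#' @param compiler A [compiler_config()].
#' @param error An [error_model_config()].
#' @param seed Default seed for sequence design and fixtures.
#' @return A `run_config` list.
#' @export
run_config <- function(std_conc_nM = 100, rates = rate_config(),
                       compiler = compiler_config(std_conc_nM = std_conc_nM),
                       error = error_model_config(), seed = 1) {
  structure(list(std_conc_nM = std_conc_nM, rates = rates,
                 compiler = compiler, error = error, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` to serialize.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    std_conc_nM = y$std_conc_nM,
    rates = do.call(rate_config, y$rates),
    compiler = do.call(compiler_config, y$compiler),
    error = do.call(error_model_config, y$error),
    seed = y$seed)
}

#' Export / import a reaction network
#'
#' Writes a flat reaction-list text file (reactants joined by `+`, `->`
#' for irreversible and `<->` for reversible reactions, one or two rate
#' constants, reaction type) together with a species CSV (id, initial
#' relative concentration, role, strand moieties) and a YAML metadata
#' file, and reads the same format back.
#'
#' @param net A `seesaw_crn`.
#' @param dir Output directory (created if needed).
#' @return `write_reaction_network` returns the directory;
#'   `read_reaction_network` returns the reconstructed `seesaw_crn`
#'   (without the originating circuit).
#' @export
write_reaction_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rx <- net$reactions
  lines <- character()
  written <- logical(nrow(rx))
  side <- function(a, b) paste(na.omit(c(a, b)), collapse = " + ")
  for (q in seq_len(nrow(rx))) {
    if (written[q]) next
    lhs <- side(rx$r1[q], rx$r2[q]); rhs <- side(rx$p1[q], rx$p2[q])
    if (!is.na(rx$rev[q])) {
      b <- rx$rev[q]
      lines <- c(lines, sprintf("%s <-> %s %.17g %.17g %s", lhs, rhs,
                                rx$rate[q], rx$rate[b], rx$type[q]))
      written[c(q, b)] <- TRUE
    } else {
      lines <- c(lines, sprintf("%s -> %s %.17g %s", lhs, rhs, rx$rate[q],
                                rx$type[q]))
      written[q] <- TRUE
    }
  }
  writeLines(lines, file.path(dir, "reactions.txt"))
  sp <- net$species
  sp$composition <- vapply(sp$id, function(id)
    paste(net$composition[[id]], collapse = ";"), character(1))
  write.csv(sp, file.path(dir, "species.csv"), row.names = FALSE,
            quote = FALSE)
  yaml::write_yaml(list(std_conc_nM = net$std_conc_nM),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_reaction_network
#' @export
read_reaction_network <- function(dir) {
  spdf <- read.csv(file.path(dir, "species.csv"), stringsAsFactors = FALSE)
  composition <- setNames(strsplit(spdf$composition, ";"), spdf$id)
  species <- spdf[c("id", "init_x", "role")]
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  lines <- readLines(file.path(dir, "reactions.txt"))
  r1 <- r2 <- p1 <- p2 <- type <- character(); rate <- numeric()
  rev <- integer()
  add <- function(lhs, rhs, k, ty) {
    r1 <<- c(r1, lhs[1]); r2 <<- c(r2, if (length(lhs) > 1) lhs[2] else NA)
    p1 <<- c(p1, rhs[1]); p2 <<- c(p2, if (length(rhs) > 1) rhs[2] else NA)
    rate <<- c(rate, k); type <<- c(type, ty); rev <<- c(rev, NA_integer_)
    length(r1)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    arrow <- which(toks %in% c("->", "<->"))
    lhs <- toks[seq_len(arrow - 1)]; lhs <- lhs[lhs != "+"]
    if (toks[arrow] == "<->") {
      ty <- toks[length(toks)]
      kf <- as.numeric(toks[length(toks) - 2])
      kb <- as.numeric(toks[length(toks) - 1])
      rhs <- toks[(arrow + 1):(length(toks) - 3)]; rhs <- rhs[rhs != "+"]
      f <- add(lhs, rhs, kf, ty); b <- add(rhs, lhs, kb, ty)
      rev[f] <- b; rev[b] <- f
    } else {
      ty <- toks[length(toks)]
      k <- as.numeric(toks[length(toks) - 1])
      rhs <- toks[(arrow + 1):(length(toks) - 2)]; rhs <- rhs[rhs != "+"]
      add(lhs, rhs, k, ty)
    }
  }
  reactions <- data.frame(r1 = r1, r2 = r2, p1 = p1, p2 = p2, rate = rate,
                          type = type, rev = rev)
  new_crn(species, reactions, composition, meta$std_conc_nM)
}

#' Path to the bundled demonstration netlist
#'
#' The two-layer, five-gate circuit jointly computing the elementary
#' cellular automaton transition rules 110 and 124 (two 2-input ORs, one
#' 3-input NAND shared by both outputs, two 2-input ANDs).
#'
#' @return File path of the netlist.
#' @export
example_netlist <- function() {
  system.file("extdata", "rule110_124.ssc", package = "seesawr",
              mustWork = TRUE)
}
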