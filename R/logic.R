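.SEESAW_OPS <- c("AND", "OR", "NOT", "NAND", "NOR")

stop_netlist <- function(msg, line = NA_integer_, class = "netlist_error") {
  prefix <- if (is.na(line)) "" else sprintf("line %d: ", line)
  stop(structure(
    class = c(class, "netlist_error", "error", "condition"),
    list(message = paste0(prefix, msg), call = sys.call(-1))
  ))
}

#' Parse a logic-circuit netlist
#'
#' Reads the line-based netlist grammar used throughout the package:
#' ```
#' # comment
#' input L
#' gate OR1 = OR(C, R)
#' output R110 = AND1
#' ```
#' Statements are `input NAME`, `gate NAME = OP(a, b, ...)` with
#' `OP` one of AND, OR, NOT, NAND, NOR, and `output NAME = net`.
#' Comments start with `#`. Every gate input must be a circuit input or a
#' gate declared on an earlier line, so circuits are feedforward by
#' construction; a reference to a gate declared later is reported as a
#' feedforward/cycle violation.
#'
#' @param text Path to a netlist file, or the netlist source itself
#'   (a single string with newlines, or a character vector of lines).
#' @return A `logic_circuit` object: ordered `inputs`, a topologically
#'   ordered list of `gates` (each with `name`, `op`, `fan_in`) and a
#'   named character vector `outputs` mapping output names to nets.
#' @export
#' @examples
#' ckt <- parse_netlist(c("input a", "input b",
#'                        "gate g = AND(a, b)", "output y = g"))
#' evaluate_circuit(ckt, c(a = 1, b = 1))
parse_netlist <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  }
  raw <- lines
  lines <- trimws(sub("#.*$", "", lines))

  name_re <- "[A-Za-z_][A-Za-z0-9_]*"
  gate_lines <- grep(sprintf("^gate\\s+(%s)\\s*=", name_re), lines)
  all_gate_names <- sub(sprintf("^gate\\s+(%s)\\s*=.*$", name_re), "\\1",
                        lines[gate_lines])

  inputs <- character()
  gates <- list()
  outputs <- character()
  defined <- character()

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^input\\b", ln)) {
      m <- regmatches(ln, regexec(sprintf("^input\\s+(%s)$", name_re), ln))[[1]]
      if (length(m) == 0) stop_netlist(sprintf("malformed input statement: '%s'", raw[i]),
                                       i, "netlist_syntax_error")
      nm <- m[2]
      if (nm %in% defined) stop_netlist(sprintf("duplicate name '%s'", nm),
                                        i, "netlist_duplicate_error")
      inputs <- c(inputs, nm)
      defined <- c(defined, nm)
    } else if (grepl("^gate\\b", ln)) {
      m <- regmatches(ln, regexec(
        sprintf("^gate\\s+(%s)\\s*=\\s*(%s)\\s*\\(([^)]*)\\)$", name_re, name_re), ln))[[1]]
      if (length(m) == 0) stop_netlist(sprintf("malformed gate statement: '%s'", raw[i]),
                                       i, "netlist_syntax_error")
      nm <- m[2]; op <- toupper(m[3])
      if (!op %in% .SEESAW_OPS) {
        stop_netlist(sprintf("unknown gate op '%s' (supported: %s)",
                             m[3], paste(.SEESAW_OPS, collapse = ", ")),
                     i, "netlist_syntax_error")
      }
      fan_in <- trimws(strsplit(m[4], ",")[[1]])
      fan_in <- fan_in[nzchar(fan_in)]
      if (op == "NOT" && length(fan_in) != 1)
        stop_netlist("NOT takes exactly one input", i, "netlist_syntax_error")
      if (op != "NOT" && length(fan_in) < 2)
        stop_netlist(sprintf("%s needs at least two inputs", op), i, "netlist_syntax_error")
      if (nm %in% defined) stop_netlist(sprintf("duplicate name '%s'", nm),
                                        i, "netlist_duplicate_error")
      for (f in fan_in) {
        if (!f %in% defined) {
          if (f %in% c(all_gate_names, nm)) {
            stop_netlist(sprintf(
              "gate '%s' references '%s' before its declaration: feedforward violation (cycle)",
              nm, f), i, "netlist_cycle_error")
          }
          stop_netlist(sprintf("undefined net '%s'", f), i, "netlist_undefined_error")
        }
      }
      gates[[length(gates) + 1]] <- list(name = nm, op = op, fan_in = fan_in)
      defined <- c(defined, nm)
    } else if (grepl("^output\\b", ln)) {
      m <- regmatches(ln, regexec(sprintf("^output\\s+(%s)\\s*=\\s*(%s)$",
                                          name_re, name_re), ln))[[1]]
      if (length(m) == 0) stop_netlist(sprintf("malformed output statement: '%s'", raw[i]),
                                       i, "netlist_syntax_error")
      nm <- m[2]
      if (nm %in% names(outputs)) stop_netlist(sprintf("duplicate output '%s'", nm),
                                               i, "netlist_duplicate_error")
      outputs[nm] <- m[3]
    } else {
      stop_netlist(sprintf("unrecognized statement: '%s'", raw[i]),
                   i, "netlist_syntax_error")
    }
  }

  for (o in names(outputs)) {
    if (!outputs[[o]] %in% defined)
      stop_netlist(sprintf("output '%s' references undefined net '%s'", o, outputs[[o]]),
                   class = "netlist_undefined_error")
  }
  if (length(inputs) == 0) stop_netlist("circuit has no inputs", class = "netlist_syntax_error")

  structure(list(inputs = inputs, gates = gates, outputs = outputs),
            class = "logic_circuit")
}

#' @export
print.logic_circuit <- function(x, ...) {
  cat(sprintf("logic_circuit: %d inputs (%s), %d gates, %d outputs (%s)\n",
              length(x$inputs), paste(x$inputs, collapse = ", "),
              length(x$gates), length(x$outputs),
              paste(names(x$outputs), collapse = ", ")))
  invisible(x)
}

.apply_op <- function(op, vals) {
  switch(op,
         AND  = as.integer(all(vals == 1)),
         OR   = as.integer(any(vals == 1)),
         NOT  = as.integer(vals[1] == 0),
         NAND = as.integer(!all(vals == 1)),
         NOR  = as.integer(!any(vals == 1)))
}

as_assignment <- function(circuit, assignment) {
  n <- length(circuit$inputs)
  if (is.character(assignment) && length(assignment) == 1) {
    bits <- as.integer(strsplit(assignment, "")[[1]])
    if (length(bits) != n || anyNA(bits) || any(!bits %in% 0:1))
      stop(sprintf("bitstring must have %d binary digits", n))
    assignment <- setNames(bits, circuit$inputs)
  }
  if (is.null(names(assignment))) {
    if (length(assignment) != n)
      stop(sprintf("unnamed assignment must have length %d", n))
    assignment <- setNames(as.integer(assignment), circuit$inputs)
  }
  missing <- setdiff(circuit$inputs, names(assignment))
  extra <- setdiff(names(assignment), circuit$inputs)
  if (length(missing)) stop("missing input(s): ", paste(missing, collapse = ", "))
  if (length(extra)) stop("unknown input(s): ", paste(extra, collapse = ", "))
  vals <- as.integer(assignment[circuit$inputs])
  if (any(!vals %in% 0:1)) stop("assignment values must be 0/1")
  setNames(vals, circuit$inputs)
}

#' Evaluate a logic circuit on one input assignment
#'
#' @param circuit A `logic_circuit`.
#' @param assignment Named 0/1 vector over the circuit inputs, an unnamed
#'   vector in input order, or a bitstring such as `"001"` (first input
#'   first).
#' @return Named integer vector of output bits.
#' @export
evaluate_circuit <- function(circuit, assignment) {
  vals <- as_assignment(circuit, assignment)
  env <- as.list(vals)
  for (g in circuit$gates) {
    env[[g$name]] <- .apply_op(g$op, unlist(env[g$fan_in]))
  }
  setNames(vapply(circuit$outputs, function(net) env[[net]], integer(1)),
           names(circuit$outputs))
}

#' Exhaustive truth table of a logic circuit
#'
#' Rows are enumerated in descending binary order of the input vector
#' (all-ones first, all-zeros last), the convention under which a 3-input
#' circuit's 8-bit output column read top to bottom is the binary form of
#' its elementary cellular automaton rule number.
#'
#' @param circuit A `logic_circuit`.
#' @param cap Maximum number of inputs for exhaustive enumeration.
#' @return A `truth_table`: data frame with one 0/1 column per input and
#'   per output, `2^n` rows.
#' @export
truth_table <- function(circuit, cap = 20) {
  n <- length(circuit$inputs)
  if (n > cap) stop(sprintf("circuit has %d inputs, exceeding the exhaustive cap %d", n, cap))
  vs <- (2^n - 1):0
  rows <- matrix(vapply(vs, function(v) as.integer(intToBits(v))[n:1],
                        integer(n)),
                 ncol = n, byrow = TRUE)
  outs <- matrix(vapply(seq_along(vs), function(i) {
    evaluate_circuit(circuit, setNames(rows[i, ], circuit$inputs))
  }, integer(length(circuit$outputs))),
  ncol = length(circuit$outputs), byrow = TRUE)
  tab <- as.data.frame(cbind(rows, outs))
  names(tab) <- c(circuit$inputs, names(circuit$outputs))
  structure(tab, class = c("truth_table", "data.frame"),
            inputs = circuit$inputs, outputs = names(circuit$outputs))
}

check_rule_bits <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 8 || any(!bits %in% 0:1))
    stop("a rule column must be exactly 8 bits (LCR = 111 down to 000)")
  bits
}

#' Elementary-CA rule number of an 8-bit transition column
#'
#' @param bits Integer 0/1 vector of length 8, ordered from neighbourhood
#'   LCR = 111 down to 000.
#' @return Integer in \[0, 255\].
#' @export
#' @examples
#' ca_rule_number(c(0, 1, 1, 0, 1, 1, 1, 0)) # 110
ca_rule_number <- function(bits) {
  bits <- check_rule_bits(bits)
  sum(bits * 2^(7:0))
}

#' Transition column of an elementary-CA rule number
#'
#' Inverse of [ca_rule_number()].
#' @param rule Integer in \[0, 255\].
#' @return 8-bit 0/1 vector, LCR = 111 down to 000.
#' @export
ca_rule_bits <- function(rule) {
  if (length(rule) != 1 || rule < 0 || rule > 255 || rule != round(rule))
    stop("rule must be a single integer in [0, 255]")
  as.integer(intToBits(rule))[8:1]
}

#' Mirror transformation of an elementary-CA rule column
#'
#' The mirrored rule assigns to neighbourhood LCR = zyx the source rule's
#' entry at LCR = xyz (left-right reflection of the neighbourhood). Applied
#' to the rule 110 column it yields the rule 124 column; the transformation
#' is an involution.
#'
#' @param bits 8-bit rule column, LCR = 111 down to 000.
#' @return 8-bit rule column of the mirrored rule.
#' @export
mirror_transform <- function(bits) {
  bits <- check_rule_bits(bits)
  out <- integer(8)
  for (v in 7:0) {
    l <- bitwAnd(bitwShiftR(v, 2), 1L)
    c <- bitwAnd(bitwShiftR(v, 1), 1L)
    r <- bitwAnd(v, 1L)
    vm <- bitwOr(bitwOr(bitwShiftL(r, 2), bitwShiftL(c, 1)), l)
    out[8 - v] <- bits[8 - vm]
  }
  out
}
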