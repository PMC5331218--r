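#' Dual-rail transformation of a logic circuit
#'
#' Translates an arbitrary feedforward AND/OR/NOT/NAND/NOR circuit into an
#' equivalent circuit containing AND and OR gates only, by representing
#' every Boolean net `x` as a complementary rail pair
#' (`x__1` carries "x is true", `x__0` carries "x is false"). Gate mapping:
#' AND becomes (AND of ON rails, OR of OFF rails); OR becomes (OR, AND);
#' NAND becomes (OR of OFF rails, AND of ON rails); NOR becomes (AND of OFF
#' rails, OR of ON rails). NOT gates emit no hardware at all: the rails are
#' simply exchanged, so chains of NOTs collapse for free.
#'
#' @param circuit A `logic_circuit`.
#' @return A `dual_rail_circuit` with fields `inputs` (original input
#'   names), `rails` (map original net -> c(on=, off=)), `gates`
#'   (AND/OR-only gate list over rail nets), `outputs` (map original output
#'   -> rail pair) and `source` (the original circuit).
#' @export
to_dual_rail <- function(circuit) {
  stopifnot(inherits(circuit, "logic_circuit"))
  rails <- list()
  for (x in circuit$inputs) {
    rails[[x]] <- c(on = paste0(x, "__1"), off = paste0(x, "__0"))
  }
  gates <- list()
  add_gate <- function(name, op, fan_in) {
    gates[[length(gates) + 1]] <<- list(name = name, op = op,
                                        fan_in = unname(fan_in))
    name
  }
  for (g in circuit$gates) {
    on_in <- vapply(g$fan_in, function(n) rails[[n]][["on"]], character(1))
    off_in <- vapply(g$fan_in, function(n) rails[[n]][["off"]], character(1))
    nm1 <- paste0(g$name, "__1"); nm0 <- paste0(g$name, "__0")
    rails[[g$name]] <- switch(
      g$op,
      NOT = c(on = unname(off_in), off = unname(on_in)),
      AND = c(on = add_gate(nm1, "AND", on_in),
              off = add_gate(nm0, "OR", off_in)),
      OR = c(on = add_gate(nm1, "OR", on_in),
             off = add_gate(nm0, "AND", off_in)),
      NAND = c(on = add_gate(nm1, "OR", off_in),
               off = add_gate(nm0, "AND", on_in)),
      NOR = c(on = add_gate(nm1, "AND", off_in),
              off = add_gate(nm0, "OR", on_in)))
  }
  outputs <- lapply(circuit$outputs, function(net) rails[[net]])
  structure(list(inputs = circuit$inputs, rails = rails, gates = gates,
                 outputs = outputs, source = circuit),
            class = "dual_rail_circuit")
}

#' @export
print.dual_rail_circuit <- function(x, ...) {
  cat(sprintf("dual_rail_circuit: %d input rail pairs, %d AND/OR gates, %d outputs\n",
              length(x$inputs), length(x$gates), length(x$outputs)))
  invisible(x)
}

# View a dual-rail circuit as a plain logic circuit over rail nets.
dr_as_logic <- function(dr) {
  rail_inputs <- unlist(lapply(dr$inputs, function(x) unname(dr$rails[[x]])))
  outs <- unlist(lapply(names(dr$outputs), function(o) {
    setNames(unname(dr$outputs[[o]]), paste0(o, c("__1", "__0")))
  }))
  structure(list(inputs = rail_inputs, gates = dr$gates, outputs = outs),
            class = "logic_circuit")
}

#' Exhaustively verify a dual-rail transformation
#'
#' For every input assignment, encodes each input `x` as the complementary
#' rail pair `(x__1, x__0) = (x, !x)`, evaluates the dual-rail circuit as
#' ordinary Boolean logic, and checks that each output's rails equal
#' `(f, !f)` where `f` is the original circuit's output.
#'
#' @param circuit Original `logic_circuit`.
#' @param dr Its `dual_rail_circuit` (or any candidate transform).
#' @param cap Maximum input count for the exhaustive sweep.
#' @return A `dual_rail_report`: list with `equivalent` (logical),
#'   `n_checked`, and a `violations` data frame naming every assignment and
#'   output rail that disagrees.
#' @export
verify_dual_rail <- function(circuit, dr, cap = 12) {
  n <- length(circuit$inputs)
  if (n > cap) stop(sprintf("%d inputs exceeds exhaustive cap %d", n, cap))
  drl <- dr_as_logic(dr)
  viol <- list()
  for (v in (2^n - 1):0) {
    bits <- as.integer(intToBits(v))[n:1]
    ref <- evaluate_circuit(circuit, setNames(bits, circuit$inputs))
    enc <- unlist(lapply(seq_len(n), function(i) {
      setNames(c(bits[i], 1L - bits[i]), unname(dr$rails[[circuit$inputs[i]]]))
    }))
    got <- evaluate_circuit(drl, enc)
    for (o in names(circuit$outputs)) {
      exp_pair <- c(ref[[o]], 1L - ref[[o]])
      got_pair <- c(got[[paste0(o, "__1")]], got[[paste0(o, "__0")]])
      if (!identical(exp_pair, got_pair)) {
        viol[[length(viol) + 1]] <- data.frame(
          assignment = paste(bits, collapse = ""), output = o,
          expected_on = exp_pair[1], got_on = got_pair[1],
          expected_off = exp_pair[2], got_off = got_pair[2])
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(assignment = character(), output = character(),
               expected_on = integer(), got_on = integer(),
               expected_off = integer(), got_off = integer())
  structure(list(equivalent = nrow(violations) == 0,
                 n_checked = 2^n, violations = violations),
            class = "dual_rail_report")
}

#' @export
print.dual_rail_report <- function(x, ...) {
  cat(sprintf("dual-rail equivalence over %d assignments: %s\n", x$n_checked,
              if (x$equivalent) "PASS" else
                sprintf("FAIL (%d violations)", nrow(x$violations))))
  if (!x$equivalent) print(utils::head(x$violations))
  invisible(x)
}
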