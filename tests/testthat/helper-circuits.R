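# Shared fixtures: circuits are built in code, no stored data needed.

rule_netlist_text <- c(
  "input L", "input C", "input R",
  "gate OR1 = OR(C, R)",
  "gate OR2 = OR(C, L)",
  "gate NAND1 = NAND(L, C, R)",
  "gate AND1 = AND(OR1, NAND1)",
  "gate AND2 = AND(OR2, NAND1)",
  "output R110 = AND1",
  "output R124 = AND2")

rule124_sub_netlist_text <- c(
  "input L", "input C", "input R",
  "gate OR2 = OR(C, L)",
  "gate NAND1 = NAND(L, C, R)",
  "gate AND2 = AND(OR2, NAND1)",
  "output R124 = AND2")

rule_circuit <- function() parse_netlist(rule_netlist_text)
rule124_sub_circuit <- function() parse_netlist(rule124_sub_netlist_text)

# two-layer AND-of-ORs circuit (the outlier/tuning demonstration shape)
two_layer_netlist_text <- c(
  "input a", "input b", "input c", "input d",
  "gate O1 = OR(a, b)",
  "gate O2 = OR(c, d)",
  "gate A1 = AND(O1, O2)",
  "output y = A1")

two_layer_circuit <- function() parse_netlist(two_layer_netlist_text)

single_and_circuit <- function()
  parse_netlist(c("input a", "input b", "gate g = AND(a, b)",
                  "output y = g"))

passthrough_circuit <- function()
  parse_netlist(c("input x", "output y = x"))

all_bitstrings <- function(n) {
  vapply((2^n - 1):0, function(v)
    paste(as.integer(intToBits(v))[n:1], collapse = ""), character(1))
}

# strand-moiety conservation: totals of each moiety over time, relative
# drift against t = 0
moiety_drift <- function(net, traj) {
  ids <- net$species$id
  moieties <- unique(unlist(net$composition[ids]))
  M <- vapply(ids, function(id)
    as.numeric(table(factor(net$composition[[id]], levels = moieties))),
    numeric(length(moieties)))
  conc <- t(as.matrix(traj[, ids, drop = FALSE]))
  totals <- M %*% conc # moieties x time
  ref <- totals[, 1]
  keep <- ref > 0
  max(abs(sweep(totals[keep, , drop = FALSE], 1, ref[keep], "/") - 1))
}
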