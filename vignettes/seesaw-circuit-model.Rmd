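---
title: "Compiling and simulating seesaw DNA circuits from unpurified strands"
author: "seesawr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling and simulating seesaw DNA circuits from unpurified strands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seesawr)
```

## The system

A seesaw gate is a reversible DNA strand-displacement motif: a
single-stranded *signal* `w(j,i)` exchanges places with an *output*
strand held on a double-stranded *gate:output* complex `G(i:i,k)` via
toehold exchange. Together with fast, irreversible *thresholds*
`Th(j,i:i)` and single-stranded *fuel*, a pair of seesaw nodes
(integrating + amplifying) computes an AND or OR over analog
concentrations and restores the result towards digital ON/OFF levels.
Arbitrary feedforward logic circuits compile onto this motif after a
dual-rail transformation that eliminates NOT gates, so a Boolean net `x`
travels on two complementary wires `x__1`/`x__0` and computation is
monotone: nothing fires until signal arrives on one of the two rails.

`seesawr` implements the full pipeline:

1. `parse_netlist()` — AND/OR/NOT/NAND/NOR netlists (feedforward,
   validated);
2. `to_dual_rail()` — AND/OR-only dual-rail equivalent (NOT is a wire
   swap and emits no hardware);
3. `compile_seesaw()` — seesaw nodes, wires, thresholds, fuels,
   reporters, and relative concentrations;
4. `design_sequences()` — three-letter-code DNA sequences per species;
5. `build_purified_crn()` / `expand_crn()` / `simulate_crn()` — the
   mass-action models;
6. the calibration toolkit — the effective-concentration calculus for
   building circuits from cheap, unpurified oligonucleotides.

## Compilation scheme and default concentrations

Every dual-rail AND/OR gate becomes one integrating node (a single
gate:output at fan-in × 1x) plus one amplifying node (one threshold, one
fuel, one gate:output per outgoing wire at 1x each). Every dual-rail
input rail gets a fan-out node (threshold, fuel, one gate:output per
consumer), even with a single consumer. Every circuit output rail gets a
reporter (1.5x). Fuel is supplied at twice the node's total gate:output
so catalysis can run to completion for every output. Inputs are 1x for
ON and 0.1x for OFF; fan-out thresholds default to 0.2x, between those
two levels. All of these are `compiler_config()` entries, not constants.
Under this counting the demonstration circuit (two 2-input ORs, a
3-input NAND with fan-out 2, two 2-input ANDs, dual-rail, 4 reporters)
enumerates exactly 78 distinct initial species in 6 layers, and its
rule-124 sub-circuit 54 — the two circuit sizes that anchor the
scheme.

Thresholds carry the logic. With ideal OFF = [0, 0.2] and ON = [0.8, 1]
bands on the integrating sum, an n-input OR threshold must exceed the
largest all-OFF sum (0.2 n) and pass a single ON (0.8); an n-input AND
threshold must exceed n − 0.8 and pass 0.8 n. The ideal defaults are the
OR band midpoint ((0.2 n + 0.8)/2, i.e. 0.6 for n = 2) and the AND lower
bound (n − 0.8, i.e. 1.2 for n = 2). `threshold_bounds()` exposes the
band arithmetic; `adjust_threshold_simple()` divides by the
threshold-to-signal ratio β/α when molecules are unpurified.

## The reaction network

`build_purified_crn()` generates five reaction types:

* **seesawing** — `w(j,i) + G(i:i,k) ⇌ G(j,i:i) + w(i,k)`, rate `k_s =
  5e4 M⁻¹s⁻¹` each direction, for every (incoming wire, output-side
  strand) pair of a node; fuel is simply one more output-side strand, so
  catalysis emerges from two coupled exchanges;
* **thresholding** — `w(j,i) + Th(j,i:i) → waste`, irreversible at `k_f
  = 2e6 M⁻¹s⁻¹`;
* **reporting** — irreversible displacement of the reporter quencher
  strand, default rate `k_f` (configurable; no separate constant is
  published);
* **leak** — blunt-end exchange: any free output-side strand displaces
  any other bound output strand at `k_l = 10 M⁻¹s⁻¹`, which lets fuel
  slowly release outputs without input;
* **binding** — universal toehold occlusion. All signal strands share
  one universal toehold, so every free strand transiently occupies the
  exposed toeholds of every double-stranded species. We model this as a
  mean-field: each free strand enters an occluded state at `k_f × L`
  (with `L` the total gate:output load) and leaves at the slow
  unimolecular rate `k_rs = 1.3 s⁻¹`.

Two points about the binding field deserve emphasis. First, the load
`L` counts gate:output complexes only: toehold exchange converts a
gate:output into a bound gate one-for-one (both expose a toehold), so
this load is rigorously constant, whereas thresholds and reporters are
consumed; restricting the field to the conserved complexes is what makes
a *constant* mean-field self-consistent. Second, `k_rs` as the
dissociation rate of a correct toehold corresponds to Kd = k_rs/k_f ≈
0.65 µM, a realistic affinity for a 5-nt toehold at 12.5 mM Mg²⁺, while
`k_rf = 26 s⁻¹` (Kd ≈ 13 µM) is the dissociation of a toehold weakened
by a synthesis error, which increases the dissociation rate. The
occlusion term matters: it slows the compiled circuit roughly eightfold
at 100 nM and is what places completion on the observed hours-long
timescale; because occupancy scales with concentration, it also largely
cancels the naive 2× slowdown expected when running at 50 nM instead of
100 nM.

Simulation is deterministic mass-action ODE integration in nM units
(`deSolve`), with an analytic Jacobian under `lsoda` for networks up to
300 species and sparse `lsodes` beyond; tolerances default to rtol 1e-8
/ atol 1e-10 nM. Strand-moiety totals are conserved to better than 1e-6
relative in all shipped tests.

## The synthesis-error (unpurified) model

Unpurified oligonucleotides carry synthesis errors at roughly `r = 0.01`
per base. The number of errors in an `l`-base strand is binomial;
molecules with more than one error are treated as non-reactive (inert),
and single-error molecules are classified by the domain carrying the
error. A 35-nt signal strand (15-nt branch-migration + 5-nt toehold +
15-nt branch-migration) therefore splits into five populations with
fractions 0.703 / 0.107 / 0.036 / 0.107 / 0.048 at r = 0.01. Complexes
partition as products over their constituent strands, carrying at most
one error in total; variant combinations whose reaction products would
carry two errors are not instantiated (they are second order in the
single-error fractions), except that terminal waste and fluorophore
sinks absorb every variant, which keeps the network finite and moiety
conservation exact.

Rates follow what mutation studies on strand-displacement motifs
establish: a toehold-domain error slows displacement
about 100-fold in every reaction type; a branch-migration error slows
only reversible, near-thermoneutral reactions (seesawing, and the
blunt-end leak exchange) about 100-fold, leaving strongly driven
thresholding and reporting unchanged. In the binding field, a toehold
error accelerates dissociation from `k_rs` to `k_rf`. The slowdown
factor φ defaults to 100 and `single_error_policy = "inert"` gives the
φ → ∞ limit, which provably equals truncating every population to its
error-free fraction. At `r = 0`, `expand_crn()` returns the purified
network object unchanged, so the purified model is the exact zero-error
limit; trajectories converge monotonically as r ↓ 0.

Interestingly, the error model reproduces the calibration phenomenology
on its own: because threshold complexes are built from shorter strands
(15 + 25 nt) than signal-bearing species, their reactive fraction is
higher, which is precisely the measured threshold-to-signal ratio β/α ≈
1.4 of unpurified molecules; and the triggered output of an unpurified
gate saturates below its nominal concentration, the γ/α < 1 effect.

## Calibration calculus

The toolkit implements the effective-concentration calculus as pure
functions plus simulation-backed estimators:

* β/α from signal restoration: `match_sim_threshold()` finds the
  simulated threshold that reproduces observed restoration trajectories
  (1-D least squares); `estimate_beta_over_alpha()` is the quotient
  against the nominal threshold. Recovery from simulated experiments
  with injected ratios 1.0–1.8 is within 5%.
* γ/α from fully-triggered gate experiments
  (`simulate_gate_calibration()`, `estimate_gamma_over_alpha()`).
* `threshold_bounds()` / `adjust_threshold_simple()` for nominal
  thresholds; `adjust_gate_nominals()` rescales gates by 0.8/(γ/α) only
  below the 0.8 acceptance floor; `adjust_outlier()` rescales an
  identified outlier by common ratio / own ratio.
* Output tuning: `delta_range()` reads the OFF excess over the ideal
  OFF value when the ON reference crosses 0.7 (lower bound) and 0.9
  (upper bound); `tune_output_threshold()` raises the output gate's
  nominal threshold by δ × α/β, refusing when OFF trajectories are not
  uniformly slower than ON.
* `advise_next_step()` encodes the systematic build procedure
  (restoration → single gate → gate calibration → two-layer → larger
  circuit) as a deterministic decision engine.

`experimental_concentrations()` applies the study's final nominal set:
thresholds 0.35x/0.85x (2-input OR/AND) and 0.4x/1.6x (3-input), fan-out
thresholds divided by β/α = 1.4, and the δ-based increase on every
output-layer threshold. The chosen δ defaults to the midpoint (0.245) of
the measured 0.08–0.41 range: the upper end maximizes OFF suppression
but, because the synthesis-error model already realizes β/α ≈ 1.4, it
raises the effective output threshold to the edge of the achievable
unpurified ON sum and stalls the circuit, while the lower end
under-suppresses OFF leak. The midpoint is the package's standing choice
and is not adjusted per circuit.

## Measurement protocol

Simulated completions are reported the way fluorescence data are: each
run is normalized with the first point of an expected-OFF rail as 0 and
the mean of the last five points of the brightest expected-ON rail as 1
(`normalize_by_expectation()`), and the completion time is the first
crossing of 0.7 by the slowest expected-ON rail. Records are 24 h for
the 50 nM ideal-threshold correctness check and 36 h for the 100 nM
kinetic benchmarks (`simulate_all_inputs()`). For the unpurified model
the normalization anchor keeps rising slowly as defective variants
trickle through (the 100-fold-slowed tail), so the reported crossing
time depends modestly on the record length; this is a limitation of any
plateau-anchored normalization applied to a process with two widely
separated timescales, and the record lengths above are fixed as part of
the protocol.

## What the synthetic fixtures do and do not show

`random_circuit()` generates feedforward netlists for property tests
(dual-rail equivalence is checked exhaustively up to 8 inputs);
`synthetic_trajectories()` produces logistic pseudo-fluorescence curves
whose crossing values are exact at zero noise, used to exercise
`delta_range()` and the tuning arithmetic against hand-computable
values. These fixtures emulate the *shape* of normalized kinetics, not
pipetting error, photobleaching, instrument drift, or sequence-dependent
synthesis quality; a passing calibration suite therefore demonstrates
the calculus and its estimators, not wet-lab performance. Likewise the
stoichiometry-excess perturbation (a configurable fraction of each
gate:output pre-released as free signal) is a deliberately crude stand-in
for annealing imbalance.

## Known limitations

* The per-reaction rate scheme for defective molecules is a
  reconstruction from the five rate constants and the 100-fold slowdown
  rules; finer per-reaction measurements would refine it. Both the
  uniform-φ scheme and the inert policy live behind
  `error_model_config()` so a refined scheme can replace them.
* The occlusion field is mean-field and constant; it ignores the ~15%
  of toehold load carried by thresholds and reporters early in a run
  and any competition between strands for the same complex.
* Sequence design enforces string constraints (three-letter code, run
  caps, Hamming separation), not thermodynamics.
* Sequential logic, XOR primitives, and stochastic (SSA) simulation are
  out of scope.
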