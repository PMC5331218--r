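# seesawr

Compile digital logic into DNA, and predict what cheap, unpurified DNA
will actually do.

`seesawr` is an R toolkit for **seesaw DNA strand-displacement
circuits**. It targets molecular programmers and DNA-nanotechnology labs
who want to go from a Boolean netlist to (i) the molecular parts list
and sequences of the corresponding seesaw circuit, (ii) quantitative
kinetic predictions by mass-action ODE simulation, and (iii) a
systematic calibration procedure for building the circuit from
unpurified (standard-desalting) oligonucleotides instead of expensive
PAGE/HPLC-purified strands.

## The model in brief

A seesaw node exchanges signal strands by reversible toehold exchange,

    w(j,i) + G(i:i,k)  ⇌  G(j,i:i) + w(i,k)        (k_s, both directions)

while double-stranded thresholds consume inputs fast and irreversibly,

    w(j,i) + Th(j,i:i) →  waste                     (k_f ≫ k_s)

Dual-rail logic (each Boolean net on an ON-wire and an OFF-wire) makes
any feedforward AND/OR/NOT/NAND/NOR circuit expressible with AND/OR
seesaw gates only; the AND/OR distinction is set purely by the threshold
concentration (ideal `th = 0.6x` for a 2-input OR, `1.2x` for a 2-input
AND). The simulator builds the full mass-action network — seesawing,
thresholding, reporting, blunt-end leak (`k_l`), and universal
toehold-binding occlusion (`k_f` on, `k_rs` off) — and integrates it
with a stiff ODE solver.

For unpurified strands, each species is partitioned by the binomial
synthesis-error model: with per-base error rate `r`, a strand of `l`
bases is error-free with probability `(1−r)^l`; single-error molecules
are classified by domain (branch-migration vs toehold) and slowed
100-fold where displacement energetics predict it; multi-error molecules
are inert. `expand_crn()` rewrites the whole network over these
populations. The calibration toolkit implements the
effective-vs-nominal concentration calculus (β/α, γ/α ratios, threshold
bounds and adjustments, outlier correction, δ-based output tuning) and a
flowchart advisor for the bench procedure.

## Worked example

The bundled demonstration netlist computes two elementary
cellular-automaton transition rules at once — rule 110 (Turing
universal) and its mirror, rule 124 — with five logic gates in two
layers, including a 3-input NAND shared by both outputs:

```r
library(seesawr)

ckt <- parse_netlist(example_netlist())
ckt
#> logic_circuit: 3 inputs (L, C, R), 5 gates, 2 outputs (R110, R124)

tt <- truth_table(ckt)           # rows LCR = 111 down to 000
ca_rule_number(tt$R110)          # 0 1 1 0 1 1 1 0  ->  110
#> [1] 110
ca_rule_number(mirror_transform(tt$R110))
#> [1] 124

ssc <- compile_seesaw(to_dual_rail(ckt), compiler_config(std_conc_nM = 50))
ssc
#> seesaw_circuit: 30 nodes, 42 wires, 78 initial DNA species, 6 layers
#>   species by role: input=6, gate_output=36, threshold=16, fuel=16, reporter=4

traj <- simulate_circuit(ssc, "001", t_end_h = 24)  # LCR = 001
round(logic_outcome(traj, read_time_h = 24)$values, 3)
#> R110__1 R110__0 R124__1 R124__0
#>   0.992   0.024   0.064   0.990
```

The four numbers are normalized reporter completions of the dual-rail
output wires after 24 simulated hours: for the neighbourhood LCR = 001
the circuit computes rule 110 = 1 (ON rail high, OFF rail low) and rule
124 = 0 — the correct transition for both rules. `design_sequences()`
then emits the 35-nt three-letter-code signal strands and complex
strands for every species (CSV/FASTA), and `expand_crn()` +
`simulate_all_inputs()` predict how much slower the same circuit runs
when built from unpurified strands.

A thin command-line wrapper is installed as `exec/seesaw`
(`compile`, `simulate`, `calibrate`, `advise` subcommands):

```sh
Rscript "$(Rscript -e 'cat(find.package("seesawr"))')/exec/seesaw" \
    compile inst/extdata/rule110_124.ssc -o out/
```

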