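Package: seesawr
Title: Seesaw DNA Strand-Displacement Circuit Compiler and Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Compiles feedforward digital logic circuits into seesaw DNA
    strand-displacement circuits via dual-rail logic, designs three-letter-code
    DNA sequences for every species, builds the corresponding mass-action
    chemical reaction networks and integrates them as ODEs under an ideal
    (purified) model and under a synthesis-error (unpurified) model in which
    each strand population is partitioned into error-free, single-error-by-domain
    and inert sub-populations. Also provides the effective-concentration
    calibration calculus for building circuits from unpurified oligonucleotides:
    threshold-to-signal and gate-to-signal ratio estimation, nominal threshold
    bounds and adjustments, outlier correction, output tuning and a systematic
    build-procedure advisor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    Biostrings,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
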