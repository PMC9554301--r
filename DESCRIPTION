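Package: kincirc
Title: Biochemical Kinetics as Transconductor-Resistor-Capacitor Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, compiles and simulates biochemical reaction networks
    expressed as electronic circuit motifs: species concentrations are node
    voltages, reaction fluxes are currents from voltage-controlled
    transconductors, first-order losses are resistors, and volume-normalized
    containers are unit capacitors.  Quasi-steady-state enzyme complexes
    become capacitor-free (algebraic) nodes, so a circuit compiles to a
    semi-explicit differential-algebraic system that is integrated with a
    stiff solver.  Ships parameterized motifs for Michaelis-Menten kinetics
    (exact mass-action and quasi-steady-state forms), competitive,
    noncompetitive, uncompetitive and mixed inhibition, product-feedback
    inhibition, two-substrate binding orders, reversible ordered Bi-Bi
    mechanisms, and repressed cell-free transcription-translation, together
    with initial-rate and Lineweaver-Burk analysis, netlist configuration
    files, synthetic noisy-assay fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
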