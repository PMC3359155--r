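Package: cpebswitch
Title: Bistable Switching in the CPEB1-alphaCaMKII Cytoplasmic
    Polyadenylation Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mass-action model of the positive feedback loop in which
    phosphorylated alphaCaMKII activates CPEB1, and phospho-CPEB1 drives
    synthesis of new alphaCaMKII through cytoplasmic polyadenylation of
    its mRNA.  Implements the full six-variable ODE system, its staged
    reductions (pseudo-steady-state elimination of the complexes to a
    three-variable model, a fitted one-variable synthesis-degradation
    model, and a steady-state quartic polynomial), fixed-point location
    and stability analysis at every model level, stimulus-driven
    switching between the basal and up-regulated states, and bifurcation
    diagrams over the degradation rate and the CPEB1 activation rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
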