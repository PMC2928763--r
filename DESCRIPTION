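Package: tbpautoreg
Title: Bistability and Dimer Buffering in a Kinetic Model of TBP Auto-Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of TATA-binding-protein (TBP)
    auto-regulation: autocatalytic Hill-type synthesis driven by
    promoter-bound TBP, sequestering dimerization, reversible DNA binding
    and first-order degradation of the free monomer. Provides steady-state
    location via a scalar fixed-point function, closed-form and numeric
    saddle-node critical values for the DNA-binding and synthesis rate
    constants, linear stability classification from the reduced Jacobian,
    one- and two-parameter bifurcation sweeps, stiff time integration and
    phase-plane analysis, and a response-time protocol quantifying how the
    dimer pool buffers perturbations in free TBP across physiological
    scenario grids.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
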