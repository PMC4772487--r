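Package: rpcompass
Title: Radical-Pair Compass Simulator with Dark-State Yield Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the spin dynamics of a radical pair coupled to an
    anisotropic hyperfine environment and an external (geo)magnetic field,
    the standard model of chemical-compass magnetoreception.  Computes the
    singlet recombination yield and decomposes it into contributions from
    the population of, and the coherence between, the two dark states of the
    two-electron Zeeman operator.  Provides the Kraus representation of the
    reduced electron dynamics together with incoherence and entanglement
    (concurrence) diagnostics, a closed-form single-nucleus solution with
    its rotating-wave yield, and Lindblad master equations for white
    magnetic-field and hyperfine-coupling noise solved exactly through the
    Liouvillian resolvent, from which the compass anisotropy under noise is
    obtained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
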