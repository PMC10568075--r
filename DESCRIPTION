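Package: pseudonull
Title: Pseudo-Nullcline Phase-Plane Analysis of Two-Module Signaling Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualitative analysis of ODE signaling models that decompose into
    two modules coupled through two scalar variables. Traces each module's
    steady-state response curve over its scalar input, projects the curves
    onto the coupling plane as pseudo-nullclines, locates and classifies
    their intersections as steady states of the full system, and tracks
    saddle-node, Hopf and saddle-homoclinic/SNIC-candidate bifurcations
    under parameter scans by deterministic sweep-and-bisection. Bundles an
    embryonic cell-cycle oscillator, a MAPK double-phosphorylation 2+2
    motif (full mass-action and reduced implicit-conservation forms), and
    analytic toy systems used as oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
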