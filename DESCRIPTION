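Package: fibrinet
Title: Multiscale Spring-Network Mechanics of Fibrin Fibers and Clots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the force-extension mechanics of fibrin at three
    coupled scales. A single fibrinogen monomer is a linear-plus-cubic
    nonlinear spring; double-stranded protofibrils are assembled from
    monomer springs, erf-saturating knob-hole (A-a) and gamma-gamma bond
    laws, and a lumped inter-protofibril binding spring, then solved in
    quasi-static equilibrium under force continuation with a trust-region
    dogleg root solver to yield single-fiber force-stretch curves; the
    fiber response is finally embedded in a modified Arruda-Boyce
    eight-chain continuum model to predict whole-clot force-stretch
    behaviour. Includes geometry derivations (monomers per cross-section,
    elements per fiber), radius and length sensitivity sweeps, YAML
    configuration round-tripping, CSV input/output, and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
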