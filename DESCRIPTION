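Package: switchcycle
Title: Modular Cell-Cycle Modeling with Ultrasensitive, Bistable and
    Delayed Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phenomenological modeling toolbox for the cell cycle built
    from three functional modules: ultrasensitive (Hill) responses,
    S-shaped bistable responses obtained by bending the Hill threshold
    with an output-dependent scaling function, and explicit time delays.
    Provides constructors for the scaling functions and switch modules,
    assembled dynamical systems (two- and three-variable embryonic
    oscillators, a delayed variant, a five-variable somatic cell cycle of
    interlinked switches, and a mass-action PP2A-ENSA-GWL oscillator),
    analysis machinery (steady states and stability, pseudo-arclength
    continuation of steady-state response curves, oscillation period and
    amplitude extraction, dynamical regime classification, cell-cycle
    phase segmentation, parameter sweeps), and scenario runners for
    checkpoint perturbations and circadian phase locking with p:q
    Arnold-tongue detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
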