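Package: ceriakin
Title: Mass-Action Kinetics of Reactive Oxygen Species Control by Ceria
    Nanoparticles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator for the four-reaction mass-action network by which
    cerium dioxide nanoparticles control reactive oxygen species: superoxide
    generation, the Ce3+/Ce4+ superoxide-dismutase couple, and the hydrogen
    peroxide catalase reaction.  Provides the dimensional and
    non-dimensional ODE systems with characteristic scales and dimensionless
    parameter groups, analytic steady-state theory (the cerous/ceric ratio
    with its disease-state and healthy-state limits, and the enumeration of
    the eight steady-state families), net-reaction thermodynamics, adaptive
    Runge-Kutta time integration with steady-state detection, and a registry
    of built-in initial-condition regimes with qualitative outcome
    classification of the superoxide trajectory.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
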