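Package: sbkernel
Title: Reaction-Network Modelling Kernel: Simulation, Composition,
    Fitting and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale kernel for executable models of biochemical
    reaction networks. Models are held in a compartmentalized attributed
    graph with an executable mathematical overlay (variables, reactions
    with kinetic laws, rules, events, constraints), read and written in
    an SBML Level 3 core subset and in a human-readable text format.
    Simulation engines cover deterministic ODE integration (Euler,
    Dormand-Prince, stiff multistep via deSolve) with event location and
    constraint halting, and exact stochastic simulation (Gillespie direct
    method, Gibson-Bruck next-reaction method, tau-leaping). Modular
    models compose by flattening or by agent-based co-simulation under a
    fixed-step scheduler. Parameter estimation uses a stochastic-ranking
    evolution strategy and particle swarm optimization against
    time-course or steady-state data with exact or relative observations.
    Structural analyses include stoichiometric relations, exact
    mass-conservation decomposition, steady-state sensitivities and
    metabolic control analysis.
License: MIT
Encoding: UTF-8
Imports:
    compiler,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
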