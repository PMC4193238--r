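Package: spikemem
Title: Memory-Scaling Theory and Reference Simulation for Distributed
    Spiking-Network Simulators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale tools for analysing the memory footprint of
    distributed spiking neuronal network simulators in the petascale
    regime.  Provides closed-form combinatorics for the distribution of
    per-source target-list lengths across virtual processes, a
    parameterised per-process memory-usage model with a maximum-filling
    solver, an alignment-aware record-layout calculator for condensed
    synapse objects, executable semantics of the adaptive (homogeneous /
    heterogeneous) connection containers with sparse presence table, a
    sparse node array with linear-estimate GID lookup, and a clock-driven
    reference simulator of the balanced random benchmark network
    (leaky integrate-and-fire neurons with alpha-shaped currents, exact
    integration, Poisson drive, static and spike-timing dependent
    plasticity synapses).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
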