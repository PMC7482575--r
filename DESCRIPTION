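Package: flocknet
Title: Collective Motion Models on Fixed Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two minimal models of collective
    motion on fixed interaction networks: a Vicsek-type heading-consensus
    model (VN) and an overdamped Active-Elastic (AE) model in which agents
    are coupled by linear springs. Provides generators for nearest-neighbour
    lattice networks, Erdos-Renyi random networks with exact node and edge
    counts, and scale-free networks built from an optimized truncated
    power-law degree sequence, together with a superposition protocol that
    interpolates between the lattice and a random topology at constant edge
    count. Includes polarization-based order-parameter sweeps over noise
    intensity, critical-noise estimation by variance-peak interpolation or
    ordered-branch loss, experiment presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
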