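Package: bicnn
Title: Bi-Hemispheric Cerebellar Network Control of a Two-Wheel Balancing Robot
Version: 0.1.0
Authors@R:
    person("bicnn", "maintainers", email = "bicnn@example.org", role = c("aut", "cre"))
Description: Builds spatially embedded rate-coded cerebellar microcircuits
    (mossy fibers, granule, Golgi, basket/stellate and Purkinje cells) wired by
    a nearest-neighbour rule under anatomical convergence ratios, encodes them
    in Address Event Representation (AER), and runs two such hemispheres as an
    adaptive controller in closed loop with a simulated two-wheel inverted
    pendulum. Directional climbing-fiber error signals with a spontaneous
    firing level drive long-term depression and potentiation at parallel
    fiber-Purkinje synapses, and a second plasticity site acts at the
    Purkinje-vestibular nucleus connection. Includes a tunable
    proportional-derivative (PD) pathway, symmetric and asymmetric
    perturbation scenarios (center/front/back loads, inclined platform),
    directional root-mean-square tracking error metrics, and a command-line
    scenario runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
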