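Package: mestweb
Title: Adaptive-Foraging Dynamics of Mutualist-Exploiter-Predator Communities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and stability analysis of mutualist-exploiter-specialist
    predator-top predator (MEST) communities in which the top predator
    reallocates its foraging effort adaptively by replicator dynamics on the
    effort simplex. Provides the coupled biomass/preference vector field with
    analytic Jacobians, trajectory integration with extinction pruning,
    bifurcation scans and Benettin Lyapunov spectra with dynamics
    classification, coexistence-equilibrium solvers and (u1, beta) stability
    maps for prescribed foraging structures, synthetic community ensembles and
    persistence-versus-connectance experiments, and signed-digraph feedback
    loop enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
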