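Package: bumptraj
Title: Moving-Bump Population Dynamics and Periodic Neural State Trajectories
Version: 0.1.0
Authors@R: person("bumptraj", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of sequential ("moving bump") neural
    population activity during rhythmic tapping. Generates moving-bump
    population activity with Gaussian cell recruitment and interval-dependent
    parameters, tapping behaviour with scalar (Weber-law) variability, and a
    non-periodic reactive control; implements tap-based event time
    normalization and binning, shared-loading principal-component state
    trajectories and their periodic geometry (radius, variability, linear
    speed, tangent-circle anchor distances, sinusoid fits, distance profiles),
    a demixed decomposition with per-parameter encoder/decoder pairs, Poisson
    surprise-index detection of single-cell activation periods, and decoding
    of tapping tempo (second-layer PCA plus linear support vector machines
    with population ablation) and of tap times (time-delay network).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
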