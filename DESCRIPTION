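Package: snippetrc
Title: Reward-Modulated Place-Cell Replay and Reservoir Consolidation of
    Navigation Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a joint hippocampus-prefrontal cortex model of spatial
    sequence learning. Short windows of place-cell activation ("snippets") are
    replayed from experienced 2D navigation trajectories with a likelihood
    shaped by temporal-difference reward propagation, in forward and reverse
    direction. A reservoir (echo state) network with a delta-rule readout
    consolidates the replayed snippets into a next-location predictor, and a
    Bayesian spatial filter closes the sensory-motor loop so that trained
    models generate trajectories autonomously. Includes arena and trajectory
    generators for multi-feeder foraging tasks, discrete Frechet distance
    trajectory comparison, and scripted, seeded reproductions of the
    consolidation, reward-rejection, recombination, reverse-replay and
    shortcut experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
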