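Package: drivenchain
Title: Monte Carlo Scattering and Machine-Learning Inversion for
    Mechanically Driven Semiflexible Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward and inverse modelling of semiflexible polymer chains
    under stretching and shear. A Metropolis Monte Carlo engine (crankshaft
    and pivot moves, hard-sphere self-avoidance) samples self-avoiding
    bead-rod chains under a driven worm-like-chain energy; the anisotropic
    two-dimensional small-angle scattering function I_xz(Q) is computed on a
    rectangular Q grid in the flow-velocity gradient plane. Scattering maps
    generated over random energy-parameter combinations are assembled into
    datasets, decomposed by singular value decomposition to assess the
    dimensionality of the scattering manifold, and inverted with per-target
    Gaussian process regression (RBF plus white-noise kernel, hyperparameters
    optimised by log marginal likelihood) to recover the bending modulus,
    stretching force, shear rate and chain conformation variables from a
    single scattering map.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
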