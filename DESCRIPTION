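Package: edafrag
Title: Fragment-Assembly Protein Structure Prediction with an Estimation of
    Distribution Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained protein structure prediction by fragment assembly
    in torsion space, where per-window fragment selection probabilities are
    learned across iterations from the lowest-energy models (an estimation of
    distribution algorithm). Provides a Rosetta-style fragment file reader and
    writer, an ideal-geometry backbone builder, Kabsch C-alpha RMSD, a
    simulated-annealing plus iterated-hill-climbing sampler with
    roulette-wheel fragment selection, the iterative distribution-update
    driver, decoy-set diagnostics (probability/RMSD correlation,
    probability-weighted fragment RMSD, energy and RMSD histogram shifts,
    near-native enrichment, energy-driven blind selection), and a synthetic
    benchmark generator with planted near-native fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
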