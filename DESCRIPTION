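Package: mekin
Title: Multi-Ensemble Kinetics and Thermodynamics from Biased and Unbiased
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators for thermodynamics and kinetics of rare-event
    processes sampled across multiple thermodynamic ensembles, such as
    ligand (un)binding studied with a mix of umbrella-sampling windows,
    well-tempered metadynamics and short unbiased molecular-dynamics
    trajectories.  Implements the transition-based reweighting analysis
    method (TRAM) for combining biased and unbiased data, reversible
    Markov state model estimation with validation diagnostics (implied
    timescales, VAMP-2 scoring, Chapman-Kolmogorov test), transition path
    theory (committors, rates, mean first-passage times), potentials of
    mean force and standard binding free energies with volumetric
    correction, well-tempered metadynamics bias reconstruction and
    reweighting, and ensemble-comparison statistics (symmetric
    Kullback-Leibler divergence, weighted contact and event probabilities,
    histogram mutual information).  A synthetic-data module generates
    Brownian-dynamics and discrete Markov-chain trajectories on model
    potentials with analytically known free energies and kinetics so every
    estimator can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
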