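Package: striatdyn
Title: Dynamics of Random Inhibitory Striatal Medium Spiny Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates local networks of striatal medium spiny neurons (MSNs)
    modelled as two-dimensional Type-1 conductance-based cells near a
    saddle-node-on-invariant-circle bifurcation, coupled by Rall-type
    inhibitory synapses on a random directed graph with
    connectivity-rescaled quenched weights, and driven by a diffusion
    approximation of thousands of independent Poisson cortical inputs with
    Pareto-distributed rates.  Includes a reduced deterministic firing-rate
    network with maximal-Lyapunov-exponent computation and dynamical state
    classification, and the population-analysis toolbox needed to study
    stimulus-locked cell-assembly dynamics: windowed firing rates, cosine
    similarity matrices and profiles, ISI statistics, relative-entropy
    firing-rate specificity, k-means assembly detection on correlation
    matrices, principal components of population rates, PSTH signal/noise
    decomposition and power spectral densities.  Sweep drivers reproduce the
    connectivity- and strength-dependent transition between
    winners-take-all and bursty-chaotic regimes at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
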