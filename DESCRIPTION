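Package: bdnflow
Title: Information Flow Capacity and Evolution of Modular Hindmarsh-Rose
    Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates brain dynamical networks of Hindmarsh-Rose neurons
    coupled by electrical (diffusive) and chemical (excitatory sigmoidal)
    synapses, estimates the two largest Lyapunov exponents by the tangent-space
    (Benettin) method, and bounds the mutual information rate between neurons
    by the information flow capacity Ic = lambda1 - lambda2.  Grows modular
    networks by greedily adding inter-cluster chemical synapses that increase
    Ic, quantifies global, pairwise and cluster-level phase synchronization
    (Kuramoto order parameter), and compares network structure via
    small-worldness, walktrap communities, modularity, degree profiles, and
    normalized-Laplacian spectral densities and distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
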