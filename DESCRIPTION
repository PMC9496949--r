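Package: fnirsnet
Title: Resting-State fNIRS Functional Network and Complexity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional near-infrared
    spectroscopy (fNIRS): conversion of two-wavelength light intensities to
    oxy-/deoxy-hemoglobin concentration changes (optical density, discrete
    wavelet motion-artifact correction, PCA removal of global physiological
    noise, zero-phase band-pass filtering, modified Beer-Lambert law),
    construction of sparsity-thresholded binary functional networks from
    Fisher-z Pearson connectivity, graph-theoretic metrics (small-worldness,
    global/local/nodal efficiency, clustering, path length) integrated over a
    sparsity range, multiscale sample entropy, N-back behavioral scoring with
    the non-parametric sensitivity index A', and between-group inference
    (network-based statistic permutation test, covariate-adjusted t-tests
    with FDR correction, partial correlations, power-based sample-size
    calculation). Includes a two-group synthetic data generator with known
    ground-truth connectivity so every stage is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
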