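Package: gmmsort
Title: Spike Sorting with Gaussian Mixture Models and Separability-Weighted Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised spike sorting for extracellular recordings built
    around Gaussian mixture models (GMMs). Waveforms are transformed into
    candidate features by principal component analysis, multiresolution Haar
    wavelet decomposition, or separability-weighted PCA on wavelet
    coefficients; each candidate feature is scored for clustering
    separability with an eight-component univariate GMM (peak, inflection
    and between-Gaussian distance metrics, or raw variance), and the
    top-ranked features are clustered by overclustering with a high-order
    mixture, Nelder-Mead density-peak search, and a final fixed-mean GMM
    classification. Includes band-pass filtering and threshold spike
    detection for raw traces, mutual-information based evaluation against
    ground truth, and a synthetic-recording simulator with template banks,
    controllable signal-to-noise ratio and firing-rate asymmetry for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    signal
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
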