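Package: eibalance
Title: Whole-Brain Excitation-Inhibition Balance Mapping from BOLD Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the Hurst exponent of parcellated BOLD time series by
    wavelet maximum likelihood as a proxy of the cortical excitation/inhibition
    ratio, fits a parametric mean-field model of coupled neural masses to static
    and dynamic functional connectivity by evolutionary search, compares groups
    region-wise with covariate adjustment and false-discovery-rate control, maps
    network spreading and disease epicenters under spatial (spin) and
    degree/length-preserving rewired null models, and classifies cases versus
    controls with leakage-free cross-validated feature selection. Ships a
    synthetic cohort generator (spherical parcellations, distance-dependent
    connectomes, fractional Gaussian noise with group-specific Hurst maps) so
    the full pipeline runs without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
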