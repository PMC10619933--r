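Package: calipr
Title: Subspace-Constrained Compressed-Sensing Reconstruction and Myelin
    Water Mapping for Multi-Echo Spin-Echo MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for highly accelerated multi-echo spin-echo (MESE)
    quantitative T2 imaging: generation of temporally incoherent
    variable-density Poisson k-space sampling schemes with calibration
    regions and elliptical shutter; extended phase graph (EPG) simulation
    of multi-echo decay with stimulated-echo contamination; digital tissue
    phantoms with known myelin water fraction ground truth and simulated
    multi-coil k-space; a two-stage subspace-constrained compressed-sensing
    reconstruction (conventional CS first pass, data-driven SVD subspace,
    FISTA with L1 wavelet regularization); regularized non-negative
    least-squares multicomponent T2 analysis with flip-angle refinement
    producing myelin water fraction and intra/extracellular T2 maps; and
    scan-rescan reproducibility statistics (Bland-Altman limits of
    agreement, repeatability coefficient, coefficient of variation, ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    Rcpp,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
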