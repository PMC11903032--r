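Package: fcvar
Title: Intersubject Variability Mapping for Seed-Based Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mapping intersubject variability of seed-based
    functional connectivity in volumetric fMRI data. Implements confound
    regression with simultaneous band-pass filtering, Fisher-z seed
    connectivity maps, voxel-wise Brown-Forsythe homogeneity-of-variance
    tests with nuisance-covariate residualization, group variability-ratio
    maps, Monte-Carlo cluster-extent correction based on residual smoothness
    estimation, smoothness-matched spatial-map permutation tests, group mean
    comparison maps, ROI-level factor correlations, and a multi-subject
    synthetic BOLD cohort generator with planted connectivity ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
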