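Package: msfnc
Title: Multiscale ICA and Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates intrinsic connectivity networks (ICNs) from 4D fMRI at
    several spatial ICA model orders (multiscale ICA), assesses their run-to-run
    stability with ICASSO-style clustering, selects ICNs by stability, spectral
    and spatial criteria, cleans their time courses, and computes static and
    tapered sliding-window dynamic functional network connectivity (FNC) across
    all within- and between-order ICN pairs.  Dynamic connectivity states are
    identified by two-stage k-means with a city-block option and an elbow rule
    for the number of states.  Group statistics include per-sex diagnosis
    contrasts from a covariate-adjusted linear model, a sex-label permutation
    test for the difference of cohort t-values, pooled false-discovery-rate
    control, domain-by-order aggregation of connectivity matrices, and
    covariate-adjusted symptom correlations.  A synthetic-data module generates
    hierarchical multiscale sources, state-switching covariance, motion
    nuisance and group effects with full ground truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
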