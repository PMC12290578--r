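Package: spinalrel
Title: Test-Retest Reliability Analysis for Task-Based Spinal Cord fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the test-retest reliability of event-related
    BOLD and peripheral autonomic responses to brief noxious stimulation.
    Provides a synthetic two-session study generator with known variance
    components, extraction of heart-period, skin-conductance and
    pupil-dilation responses, slice-wise cardiac/respiratory (RETROICOR-style)
    nuisance regressors, voxel-wise first-level GLMs with double-gamma HRF
    convolution, one-sample sign-flipping permutation inference with
    max-statistic family-wise error control, region-of-interest amplitude
    metrics, Dice spatial overlap, and ICC(3,1) reliability estimates with
    F-based confidence intervals and Cicchetti interpretation bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
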