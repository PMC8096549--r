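Package: nhkit
Title: Default-Mode Network Homogeneity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network homogeneity (NH) analysis of resting-state
    BOLD fMRI in clinical group designs. Provides a synthetic-cohort
    generator with known ground truth, standard temporal preprocessing
    (volume discard, linear detrending, frequency-domain bandpass
    filtering, Friston-24 plus tissue-signal nuisance regression,
    framewise-displacement motion quality control), group spatial ICA with
    template-based default-mode-network mask construction, per-voxel NH
    maps with mask-restricted Gaussian smoothing, voxelwise ANCOVA and
    post-hoc t contrasts with Gaussian random field cluster-extent
    correction, summary-statistic clinical tests with Benjamini-Hochberg
    adjusted NH-symptom correlations, and leave-one-out support vector
    machine classification over cluster-NH feature combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
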