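Package: scnmapr
Title: Seed-Based Structural Covariance Network Mapping for Voxel-Based
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps structural covariance networks (SCNs) from preprocessed
    gray-matter volume images. Provides seed-sphere signal extraction at
    MNI coordinates, mass-univariate voxel-wise regression with nuisance
    covariates, family-wise-error height and extent thresholding
    (Bonferroni and Freedman-Lane permutation max-T), between-group
    covariance-slope interaction contrasts with treatment coding, and
    hemispheric network-extent trajectory summaries across age groups.
    Includes a synthetic-cohort generator with planted covariance
    networks so every pipeline stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    igraph,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
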