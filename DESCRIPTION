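Package: congradr
Title: Local-Global Connectopic Gradient Mapping for Volumetric fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes connectopic functional gradients of a seed region from
    resting-state fMRI timeseries under four fingerprint variants (the
    original SVD-based formulation, a singular-value-rescaled variant, a
    direct voxelwise variant, and a within-seed functional-connectivity
    variant), embeds voxel-to-voxel similarity matrices with Laplacian
    eigenmaps, diffusion map embedding, or PCA, and aligns individual
    gradients to a group template via Hungarian matching and orthogonal
    Procrustes. Includes downstream analyses (representational similarity
    analysis of gradient geometry, discriminant prediction of nucleus
    labels, nested cross-validated sparse phenotype prediction), a
    synthetic-cohort generator with planted gradient structure, lightweight
    NIfTI-1 input/output, and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    clue,
    glmnet,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
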