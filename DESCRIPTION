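Package: longsem
Title: Longitudinal Measurement Invariance, Second-Order Growth Curves and
    Voxel-Wise Structural Equation Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling change in a repeatedly administered
    multi-item scale and relating it to voxel-wise brain structure. Provides
    a mean-and-covariance-structure SEM engine with full-information maximum
    likelihood for monotone and intermittent dropout, effects-coding
    identification, robust (sandwich) standard errors and a
    Satorra-Bentler-style scaling factor; chi-square fit statistics with
    RMSEA (noncentral 90% confidence intervals) and CFI; sequential
    configural/weak/strong measurement-invariance testing with
    modification-index-driven partial invariance search; second-order latent
    growth curve models with time-invariant covariates; a massively
    univariate voxel-wise stage that predicts the latent slope or intercept
    from each in-mask voxel with cluster-extent thresholding of the
    resulting 3D statistic maps; and a synthetic-data generator with known
    ground truth for item panels and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
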