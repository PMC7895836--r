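Package: ectfield
Title: Voxel-Wise Electric Field to Outcome Analysis for Electroconvulsive Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Relates simulated electroconvulsive therapy (ECT) electric-field
    strength to clinical outcome with a mass-univariate "inverse" general
    linear model in which the per-voxel field magnitude is the independent
    variable and the depression score the dependent variable, adjusting for
    clinical covariates. Inference uses threshold-free cluster enhancement
    (TFCE) with max-statistic permutation testing for family-wise error
    control: sign-flipping for the paired bilateral-versus-right-unilateral
    field comparison and Freedman-Lane outcome permutation for the covariate
    adjusted regression. Includes NIfTI volume handling on a common grid,
    field magnitude scaling from unit-current solutions to device output,
    cluster extraction with effect-size summaries, and a synthetic-cohort
    generator emulating common-space field stacks with smooth spatial
    covariance and planted effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
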