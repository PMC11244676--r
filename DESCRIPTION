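Package: metartiq
Title: Objective Metal-Artifact Quantification for CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify metal artifacts in computed tomography
    volumes around high-density implants such as left-ventricular assist
    devices: region-of-interest attenuation metrics (mean HU difference and
    artifact-region standard deviation), a Fourier streak statistic measured
    along a contour surrounding the metal, and a blooming-volume metric from
    HU-threshold segmentation with largest-connected-component filtering.
    Includes the statistical layer of a visual-grading observer study
    (score tallying, intraclass correlation, baseline-category multinomial
    logit models, Spearman correlation matrices, and log-linear regression
    of artifact metrics on acquisition and reconstruction covariates), a
    synthetic CT phantom generator with controllable blooming, streak and
    noise artifacts plus simulated ordinal reader scores, and bundled
    per-case study tables for a phantom and an in-vivo LVAD acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    nnet,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
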