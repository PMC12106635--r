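Package: vasofiber
Title: Mapping White-Matter Vessel Orientations and Their Alignment with
    Fiber Orientations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the orientation of cerebral white-matter
    vasculature from susceptibility-weighted MRI and quantifying its angular
    alignment with diffusion-derived fiber orientations. Implements
    susceptibility-weighted contrast construction (homodyne high-pass phase
    filtering, phase masking, magnitude weighting, repetition averaging),
    multiscale Frangi vesselness filtering with Hessian-based tube-axis
    extraction, vessel segmentation with tissue-boundary exclusion, axial
    (sign-invariant) orientation statistics with dyadic averaging, spherical
    harmonic fiber-orientation-distribution peak extraction by Newton search
    on the sphere, voxel-wise dominant and nearest vessel-fiber angle maps,
    atlas region summaries, along-tract angle profiles over 100 segments,
    and population-level orientation averaging with preservation-of-
    principal-direction reorientation. A synthetic phantom module generates
    ground-truth tube images, spherical-harmonic fields, and streamline
    bundles so the full pipeline is verifiable without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
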