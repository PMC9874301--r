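Package: bonemorph
Title: Dual-Resolution MicroCT Morphometry of Subchondral Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how lower-resolution in vivo microCT imaging
    biases three-dimensional morphometric measurements of subchondral
    trabecular and cortical bone relative to high-resolution ex vivo imaging.
    Provides implicit-geometry bone phantoms with known ground truth and a
    simulator of paired acquisitions at two voxel sizes; the full
    preprocessing chain (Gaussian smoothing, automatic two-peak global
    thresholding, 6-connectivity component filtering, despeckling, rigid
    registration by normalized mutual information with Lanczos resampling);
    programmatic trabecular and cortical regions of interest; the standard
    3D morphometry suite (BV/TV, BS/BV, Tb.Th, Tb.Sp, Tb.N, DA, SMI, Conn.D,
    Ct.Th) via Euclidean distance transforms, maximal-sphere local thickness,
    mean-intercept-length fabric tensors, marching-cubes surfaces and
    Euler-characteristic topology; and paired accuracy statistics
    (paired t-tests, linear regression, Bland-Altman agreement, Monte-Carlo
    Lilliefors normality, two-sample group comparison) with table-style
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
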