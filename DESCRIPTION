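Package: cartthick
Title: Cartilage Thickness Measurement from Segmented Knee MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures articular cartilage thickness from segmented 3D knee MRI
    label volumes using five automatic methods: 3D mesh normals, 3D nearest
    neighbors, 3D ray tracing, 2D centerline normals, and 2D surface normals.
    Implements the standardized femorotibial parcellation into four regions and
    twenty subregions (medial/lateral split, 20%-volume central cylinder, tibial
    quadrants, femoral thirds), per-sample and per-(sub)region summaries, and
    the full inter-method agreement analysis (5-SD outlier screening, repeated
    measures ANOVA with Tukey-Kramer post hoc tests, Bland-Altman limits of
    agreement, Lin's concordance correlation coefficient). Reads and writes
    MetaImage and NIfTI label volumes and ships analytic phantom generators
    (slabs, spherical shells, a composite knee) with known ground-truth
    thickness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    RANN,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
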