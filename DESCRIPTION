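Package: wingmark
Title: Two-Tier Landmark Detection and Alignment QC for Insect Wing Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, end-to-end workflow for locating the 11 vein-intersection
    landmarks used in geometric morphometrics of tsetse (Glossina spp.) wing
    images. A first-tier binary classifier removes incomplete wings (those
    missing landmark 4 or 6), and a second tier localises landmarks either by
    direct coordinate regression or by per-landmark disk segmentation with a
    seventh-highest-value centroid inference rule. The package also provides
    joint image/keypoint affine augmentation, bootstrap evaluation of
    classification metrics, pixel-distance error summaries, generalized
    Procrustes shape-bias analysis, finite-population sample statistics, and
    page-level wing-length quality control that detects image-to-record
    misalignments. A synthetic wing generator with known ground truth makes
    every stage testable without real data, and a small built-in neural-network
    engine lets the full training protocol run on a CPU at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
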