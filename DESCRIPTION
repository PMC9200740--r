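Package: hictriad
Title: Multi-Level Differential Hi-C Analysis of Compartments, CTCF Loops,
    and Enhancer-Promoter Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing three-dimensional genome organization
    between conditions from binned Hi-C contact data at three levels:
    A/B compartment eigenvectors with quartile-shift differential calls,
    punctate CTCF loop detection with master-list merging and
    fold-change differential loops, and binomial distance-model
    significant interactions with loop exclusion and enhancer-promoter
    classification. Includes matrix balancing, distance normalization,
    equal-depth downsampling, aggregate peak analysis, insulation
    scores, X-escapee expression calls, and a synthetic Hi-C generator
    that plants known compartments, loops, and interactions so every
    stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
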