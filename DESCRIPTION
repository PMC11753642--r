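Package: mothflame
Title: Moth-Flame Optimization Feature Selection for Disease Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building wrapper feature-selection pipelines
    for plant-disease image classification. Provides a continuous Moth-Flame
    Optimization (MFO) engine with elitist flame memory and logarithmic-spiral
    position updates, a binary MFO wrapper that selects feature subsets by
    cross-validated classifier error plus a subset-size penalty, serial (array
    concatenation) fusion of feature tables, label-preserving image augmentation
    (90-degree rotation and both flips), a deterministic block-statistics feature
    extractor, a registry of ten classifier presets with a multiclass evaluation
    metric suite, and seeded synthetic-data generators (Gaussian feature matrices
    with a planted informative subset, and lesion-on-leaf toy images) so every
    stage is testable end to end without external datasets or pretrained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
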