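Package: phybite
Title: Phylogenetic Prediction of Jaw-Muscle Cross-Sections and Bite Force
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian phylogenetic predictive modelling of muscle physiological
    cross-sectional areas (A_Phys) from skull width under Brownian motion on a
    time-scaled phylogeny, with posterior predictive distributions for tips
    whose response is unobserved (e.g., fossil taxa). Includes leave-one-out
    cross-validation with posterior predictive p-values, calculators for
    physiological cross-sectional area from muscle architecture and from gross
    cross-sections with pennation corrections, paleontological tree
    time-scaling from stratigraphic ranges, a static lever model converting
    predicted areas into bilateral bite forces, and a synthetic-data generator
    for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
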