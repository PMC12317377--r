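Package: soundmvpa
Title: Multivoxel Pattern Decoding of Natural Sound Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for decoding semantic sound
    categories from multivoxel fMRI activity patterns. Implements the full
    analysis chain for a hierarchical natural-sound listening experiment:
    taxonomy encoding and pseudo-randomized trial scheduling, synthetic
    multi-participant voxel-pattern and BOLD time-series generation,
    event-wise beta estimation by ordinary least squares, condition
    averaging with leave-one-run-out linear support-vector-machine
    classification, group-level permutation inference with effect sizes,
    whole-volume searchlight mapping with Monte-Carlo cluster-size
    correction, acoustic stimulus controls (power spectral density,
    harmonics-to-noise ratio, amplitude envelope and attack), and
    one-sample power analysis utilities.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
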