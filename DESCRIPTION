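Package: connseg
Title: Network Segregation Analysis of ROI Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for resting-state network-segregation
    analysis of region-of-interest (ROI) functional connectomes. Converts
    per-subject ROI time series into Fisher z-transformed correlation
    matrices, binarizes them at a range of proportional thresholds, derives a
    reference modular organization from healthy-control data by Ward
    hierarchical clustering, and computes threshold-averaged participation
    coefficients together with within-module, between-module, per-module and
    per-hemisphere connection counts for target nodes. Includes the
    longitudinal statistical battery used in tDCS intervention studies
    (pre-treatment group and severity regressions, treatment-arm change
    models, paired and independent t tests, a brain-behavior interaction
    model, and Benjamini-Hochberg FDR correction), and a planted-partition
    synthetic-cohort generator so the entire pipeline can be validated
    against known ground truth without imaging data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
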