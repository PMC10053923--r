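Package: fusemet
Title: Concatenated MS-NMR Metabolomics of Seasonal Plant Harvests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for mid-level data fusion of
    LC-MS feature tables and 1D J-resolved NMR projection spectra in
    untargeted plant metabolomics. Provides spectral binning (bucketing),
    MZmine-style feature-table curation (solvent-blank removal, external
    standard QC), accurate-mass arithmetic with molecular-formula
    prediction and library dereplication, block-wise variance scaling for
    two-block fusion, natively implemented NIPALS PLS-DA and OPLS-DA with
    VIP scores, seven-fold Q2 cross-validation and permutation validation,
    and rank-based false-discovery-rate selection of discriminant
    features. A synthetic seasonal-study generator with planted
    ground-truth discriminants makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
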