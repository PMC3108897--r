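Package: bxdnet
Title: Expression QTL Mapping and Co-Expression Networks for Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for systems-genetics analysis of array-style expression
    data from recombinant inbred (RI) strain panels such as the BXD family.
    Implements per-array global normalization onto the 2z+8 scale, per-transcript
    genome scans by likelihood ratio statistic (LRS) marker regression with
    cis/trans classification, trans-band (signature QTL) detection over trait
    collections, Pearson correlation and partial-correlation network tools, and
    a candidate-gene search-and-refinement workflow. A synthetic RI-panel
    generator with a known eQTL architecture provides ground truth for every
    stage.
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
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
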