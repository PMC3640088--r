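Package: barcodeaudit
Title: Quality Auditing for DNA Barcode Reference Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heuristic quality control for large collections of fungal ITS
    DNA barcodes anchored to vouchered herbarium specimens. Computes pairwise
    base-pair difference matrices with a retention cap for distant pairs,
    barcode-gap profiles of within- versus among-species divergence,
    false-negative and false-positive barcode error detection with a
    taxonomic severity ladder, ITS1/ITS2 mini-barcode evaluation via
    distance-matrix correlation, UPGMA and NMDS concordance checks of
    specimen identifications against taxonomy, and contingency analysis of
    PCR amplification success by specimen age and taxon with adjusted
    residual post-hoc tests. A synthetic herbarium generator with known
    ground truth supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
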