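Package: poolscreen
Title: Deconvolution and Statistical Analysis of Pooled shRNA Barcode Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for next-generation-sequencing readout of pooled shRNA
    barcode screens. Short sequencing reads are trimmed to the 19-nucleotide
    sense sequence, binned, and assigned to a reference hairpin library by
    minimal hamming distance with best-stratum ambiguity exclusion. Per-hairpin
    count matrices are normalized by robust loess regression of the log ratio
    on mean log abundance, rescaled by the pool median absolute deviation,
    optionally quantile normalized across replicates, and summarized into
    hairpin scores. Hits are called from a quantile-quantile departure
    threshold and genes ranked by a weighted-average score with permutation
    p-values. An engineered-depletion simulator and evaluator quantify screen
    sensitivity (false negative rate at a zero-false-positive threshold,
    depletion ratio recovery, replicate reproducibility, read-depth
    subsampling), and a planner computes the cell, DNA and PCR arithmetic of
    screen designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
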