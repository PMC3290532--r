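Package: repeatscape
Title: Repeat Landscape Comparison from Genome Survey Clone Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the repetitive-DNA landscape of a genome from a
    random short-insert clone library and compares two genomes family by
    family. Clones are classified against a panel of repeat-family probe
    sequences by thresholded local alignment (an in-silico surrogate for
    filter hybridization, one clone counted as one hit), hit counts are
    scaled by the library's genome-coverage fraction to copies per genome
    and genome fractions with exact binomial confidence intervals, and the
    two species are contrasted through fraction ratios in a hierarchical
    category table. Also detects perfect microsatellite runs with primitive
    repeat units, and builds per-position genomic copy-number profiles
    along reference elements from read similarity hits under Karlin-Altschul
    E-value filtering. A synthetic-genome simulator with full placement
    ground truth (LTR retrotransposons with solo-LTR derivatives, tandem
    satellites, dispersed elements) makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
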