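Package: duphist
Title: Reconstructing Gene Family Duplication Histories in Related Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for reconstructing the duplication
    history of a gene family across related genomes. Implements
    homology-based paralog and ortholog calling from pairwise local
    alignment, Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction and selection-regime classification, microsynteny block
    detection from flanking-gene homology, tandem-duplication
    classification, median-Ks dating of duplicated blocks against known
    whole-genome-duplication eras, an ancestral-locus retention matrix, and
    neighbor-joining phylogenies with bootstrap support. A synthetic-genome
    simulator plants whole-genome, segmental and tandem duplications at
    controlled synonymous divergence and omega, providing ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
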