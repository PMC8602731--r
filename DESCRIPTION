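Package: bgcdiel
Title: Biosynthetic Gene Cluster Inventory and Diel Expression Dynamics
    in Soil Biocrust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and analysis of biosynthetic gene cluster (BGC)
    annotations and wet-up metatranscriptome time series from biological soil
    crust. Implements BGC inventory bookkeeping (contig-length eligibility,
    full-length determination from contig edges, novelty classification from
    nucleotide alignment hits, best-hit taxonomy assignment), the diel
    expression pipeline (low-count filtering, total-count normalization,
    replicate averaging to timepoints, z-score profiles, constitutive
    transcription classification, transcription breadth, day/night peak
    assignment), and Pearson co-occurrence network analysis at the BGC and
    phylum level with multiple-testing correction. A synthetic-data generator
    emulates the 13-sample, 10-timepoint wetting experiment with known ground
    truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
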