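Package: editscan
Title: Detection and Analysis of A-to-I RNA Editing from RNA-Seq Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of putative RNA-editing sites from per-base RNA-seq
    pileups mapped to unspliced gene-space transcript models, as used to study
    adenosine-to-inosine (A-to-I) editing during sexual development of
    filamentous ascomycetes. Provides a samtools-mpileup parser, threshold-based
    variant detection with replicate-reproducibility filtering and a
    genome-error screen, substitution-spectrum statistics normalized per million
    covered bases, codon-consequence classification including stop-loss
    read-through, cross-species comparison of edited orthologs by global protein
    alignment, per-clone co-editing analysis against a Poisson-binomial
    independence null, expression-group association summaries, and a synthetic
    RNA-seq data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
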