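Package: refguide
Title: Reference-Guided De Novo Genome Assembly and Multi-Statistic Assembly Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained reference-guided de novo assembly pipeline for
    short-read data from species with a sequenced relative. Reads are quality
    trimmed, mapped to the related reference with a built-in seed-and-extend
    mapper, partitioned into overlapping superblocks of continuous coverage,
    de novo assembled per superblock with a built-in multi-k de Bruijn
    assembler, merged into non-redundant supercontigs by homology-guided
    layout and consensus, rescued for diverged regions by re-assembling
    unmapped reads, error corrected from read pileups, and scaffolded with
    ranked mate-pair libraries. A companion evaluation framework computes
    continuity, accuracy and misassembly statistics against a truth genome
    and ranks assemblies by summed z-scores with leave-one-out error bars and
    one-sided Wilcoxon rank-sum comparisons. Includes a diploid Illumina-like
    read simulator for heterozygous genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
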