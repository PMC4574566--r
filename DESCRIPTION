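Package: hybscreen
Title: In Silico Hybridization Screening for Protein-Coding Variant Loci
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers un-annotated genomic loci encoding proteins similar to
    a query protein by degenerate reverse translation: short peptide windows
    of the query are expanded into every synonymous-codon DNA realization and
    matched exactly against both strands of a genome, so hits are robust to
    synonymous divergence. Nearby hits are merged into candidate loci, open
    reading frames are reconstructed and filtered on peptide length and
    in-frame coverage of the query core domain, and candidates are
    characterized by Levenshtein distance, hierarchical sequence grouping,
    diagnostic residue motifs, and 3'-end structure (histone stem-loop versus
    polyadenylation signal). Includes gene-annotation context summaries
    (promoter/gene-body/intergenic fractions, peak category proportions,
    putative 3'-UTRs, RPM quantification) and a seeded synthetic-genome
    simulator with ground truth for end-to-end validation. Ships reference
    histone H3 sequences and defaults tuned for histone H3 variant discovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
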