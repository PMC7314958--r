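Package: straindiff
Title: Strain-to-Strain Genome Comparison for Fungal Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two closely related fungal strains at the genome level:
    classifies variants (SNPs, short indels) against reference gene models into
    region and coding consequence (amino acid changes, frameshifts, variants in
    consensus splice sites), aggregates per gene and per CAZy-style family,
    calls gene presence/absence by two-stage homology search, finds orthologs
    by reciprocal best hits, and tests functional groups for overrepresentation
    with the hypergeometric distribution. Includes a seeded synthetic-genome
    simulator that emits a reference strain plus a mutated derived strain with
    truth-labelled variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
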