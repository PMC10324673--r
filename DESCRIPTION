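Package: longstar
Title: Long-Read Star-Allele Genotyping of the CYP2D6-CYP2D7-CYP2D8 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for full-locus CYP2D6 star-allele genotyping
    from CRISPR-excised long reads. Models the CYP2D6-CYP2D7-CYP2D8 segmental
    locus, performs in-silico Cas9 digestion, simulates nanopore-like reads
    with truth labels, applies read-level quality gates, classifies structural
    variants (full-gene deletion, duplication, hybrid tandems) against custom
    reference tracks using spacer-gap detection, and phases the two parental
    alleles directly from full-span reads to call star alleles, suballeles,
    and formatted diplotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
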