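Package: TransloMap
Title: Detection and Characterization of Large Reciprocal Translocations
    from Linkage, Mate-Pair and Junction Evidence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and characterize large reciprocal chromosomal
    translocations relative to a reference genome assembly. Implements
    pairwise linkage scanning of selfed F2 progeny genotypes to locate
    complete linkage breaks and trans-chromosome linkage blocks,
    classification and clustering of discordant large-insert mate pairs
    with combinatorial reconstruction of chromosome structures from
    adjacency constraints, signature-segment-junction (SSJ) genotyping of
    accession panels with positive-evidence-only semantics, and
    dissimilarity-based principal coordinates analysis with supplementary
    projection. A deterministic synthetic-data generator produces
    desk-scale rearranged genomes, read pairs with truth alignments,
    selfed progeny genotypes and structured accession panels so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
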