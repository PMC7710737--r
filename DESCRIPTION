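Package: rnparch
Title: Modular Architecture Analysis of Long Noncoding RNA-Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves the modular architecture of long-RNA ribonucleoprotein
    complexes from sequencing data mapped to a mature-transcript mini-genome.
    Detects proximity-ligated chimeric fragments in paired-end RIP libraries
    and clusters them into long-distance groups; builds input-normalized
    binding profiles in fixed windows and discovers domain structure by
    hierarchical clustering and principal component analysis; averages signal
    over tandem repeat units and scans degenerate IUPAC motifs; tests
    cross-species duplex-group overlap with a length-preserving shuffle
    permutation test; quantifies IP-versus-input enrichment in predefined
    transcript domains relative to a reference allele; and calls crosslink-site
    clusters from irCLIP alignments. A synthetic-data module generates
    transcripts, alignments, coverage tracks, duplex-group sets and crosslink
    pileups with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
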