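Package: TandemTRIM
Title: Detection and Quantification of Cassandra TRIM Retroelement Tandem Arrays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering Cassandra terminal-repeat retrotransposons
    in miniature (TRIMs) and their long tandem arrays in plant genome
    sequences. Implements a distance-constrained degenerate-motif linked
    search over IUPAC nucleotide codes, tandem-array chaining, element
    annotation (LTR, internal domain, primer binding site), an in silico PCR
    predictor for the amplicon ladders produced by inverted primers on tandem
    templates, copy-number arithmetic for qPCR standard curves and dot-blot
    hybridization, a palindromic stem score for LTR self-complementarity, and
    a seeded synthetic-genome generator with truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Annotation, SequenceMatching, Transposon, Genetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
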