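Package: polyAcontext
Title: Sequence-Context Analysis of Poly-Alanine Regions in Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and characterisation of pure and impure poly-alanine
    (polyA) homorepeats in protein sequences. Provides sliding-window
    detection of alanine-rich tracts, composition and enrichment statistics
    for impurities and for the -10..+10 flanking positions, positional
    statistics of repeats within proteins and their relation to predicted
    mitochondrial transit peptides, signal peptides and subcellular
    location, tripeptide-based secondary-structure propensity profiles over
    repeats and flanks, and alignment-based classification of repeat
    emergence (insertion versus substitution). A synthetic-proteome
    generator with a ground-truth ledger supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Proteomics, SequenceMatching, Alignment, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
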