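Package: spliceLoop
Title: Simulation and Analysis of Heteroduplex-Trapped Alternative Splicing
    cDNA Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for alternative-splicing-enriched cDNA libraries built by
    heteroduplex trapping. Provides a sequence-level simulator of the library
    protocol (variant hybridization, exonuclease trimming, DpnII digestion,
    single-strand loop capture with 25-mer oligos, PCR redundancy, read
    emission with a ground-truth manifest) and the downstream pipeline:
    windowed quality trimming, greedy overlap clustering into consensus tags,
    spliced-alignment filtering by identity and coverage, pairwise exon/intron
    boundary comparison classifying exon skipping, intron retention and
    alternative 5'/3' splice sites, premature-termination-codon scanning with
    the 50-nt nonsense-mediated-decay rule, and reference-gene-normalized
    expression balance with signed fold changes, including ligation-probe
    design for variant-specific assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
biocViews: AlternativeSplicing, Transcriptomics, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'transcript-model.R'
    'alignment.R'
    'utils.R'
    'balance.R'
    'coding.R'
    'events.R'
    'read-processing.R'
    'simulate.R'
    'pipeline.R'
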