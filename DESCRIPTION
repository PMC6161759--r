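Package: intronAudit
Title: Auditing Putatively Very Small Introns in Genome Annotations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to audit ultra-small predicted introns in a genome
    annotation. Derives per-isoform introns from a FASTA genome plus GFF3
    gene models and computes intron-size censuses; screens microintron
    candidates with exclusion rules (no co-amplifiable control intron, no
    primer site) and tandem-repeat risk flags; designs RT-PCR primer pairs
    whose amplicon spans both the candidate and a control intron so that
    splicing evidence can discriminate cDNA from genomic DNA; classifies
    sequenced amplicons by spliced alignment against the locus with
    GT..AG-aware boundary refinement (confirmed, absent, larger than
    predicted, extra splicing, or genomic/unable-to-judge); and summarises
    verification panels. A synthetic-data module generates toy genomes with
    planted annotation errors (false microintrons, boundary shifts, extra
    introns, pseudogenes, repeat-induced mispredictions) so the whole
    pipeline is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Annotation, Alignment, SequenceMatching, GenomeAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
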