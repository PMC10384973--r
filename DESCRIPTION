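Package: VectorTxAudit
Title: ORF-Centric Transcript Classification and Splice Audit for Adenovirus Vector Genomes from Direct RNA Long Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies spliced long-read (nanopore direct RNA) alignments against an
    annotated adenovirus vaccine vector genome. Reads are canonicalized by snapping
    splice junctions to catalogued donor/acceptor sites and assigning 5' ends to
    transcription start sites and 3' ends to polyadenylation sites, then collapsed
    into transcript groups with frequencies. Each group receives a 5'-proximal
    open-reading-frame call on its reconstructed mature mRNA (catalog ORF or a
    translated novel peptide), from which per-ORF gene transcription tables, a
    transgene-cassette aberrant-splicing audit, and a replication-competent
    adenovirus (E1 transcript) screen are derived. A synthetic direct-RNA read
    generator with ground truth makes the whole pipeline testable without external
    data.
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
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
biocViews: Transcriptomics, LongRead, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
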