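Package: nbipscan
Title: Bidirectional Promoter Discovery and Novel Transcript Classification
    from Strand-Specific Brain RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for classifying de novo assembled transcript
    contigs against a reference annotation and discovering a class of novel
    bidirectional promoters (NBiPs) formed by protein-coding genes and
    unannotated upstream-antisense lncRNAs. Implements strand-aware contig
    clustering and known/novel status calls, detection of novel elements of
    annotated genes (internal exons, splice-site variants, UTR extensions),
    sense/antisense gene-pair geometry and expression-correlation contrasts,
    genomic-context classification of intergenic transcripts with
    permutation-derived distance cutoffs, CAGE-based divergent-transcription
    promoter typing (UniP/KBiP/NBiP), promoter sequence and epigenetic feature
    contrasts, MATCH-style position-weight-matrix scanning with
    dinucleotide-shuffle null profiles and binding-site enrichment, and
    developmental expression dynamics (polynomial age tests with permutation
    FDR, trajectory clustering, tissue specificity, strandedness QC). A
    synthetic-data generator emits a fully self-consistent toy dataset with
    planted structure so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
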