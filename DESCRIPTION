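Package: sorfcons
Title: Discovery and Evolutionary Analysis of Conserved Small Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for the discovery of conserved small open
    reading frames (sORFs) in annotated transcriptomes. Scans spliced
    transcripts for AUG-initiated ORFs, groups and classifies them by genomic
    context, extracts codon-level and nucleotide-level conservation features
    from multiple-species alignments and conservation tracks, predicts coding
    sORFs with a linear support-vector machine, and removes predictions whose
    conservation signal cannot be unambiguously assigned. Downstream analyses
    cover SNP-based dN/dS selection tests, cross-species homology clustering
    of the encoded peptides, ancestral-conservation inference, peptide
    usage/disorder/motif properties, ribosome-profiling translation calling
    (ORFscore), expression specificity, and diagnostics for 3'UTR sORFs.
    Includes a synthetic-data generator that emulates every input format with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    ape,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
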