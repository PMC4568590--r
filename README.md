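# sorfcons

Discovery and evolutionary analysis of conserved small open reading frames
(sORFs) in annotated transcriptomes.

## The problem

Transcripts and transcript regions annotated as non-coding — lincRNAs,
5'/3'UTRs, "other" transcripts of coding loci — are full of short
AUG-initiated ORFs that arise by chance. A small minority encode functional
micropeptides. Because short ORFs carry too little signal for
sequence-statistics methods, `sorfcons` targets the evolutionary signatures
of purifying selection on the *encoded peptide*: depletion of
non-synonymous substitutions across species, absence of frameshifting
indels, and the characteristic step in nucleotide conservation at ORF
boundaries. It is aimed at computational biologists who have a transcript
annotation, whole-genome multiple alignments and a conservation track, and
want a ranked, filtered catalog of candidate micropeptide ORFs plus the
downstream evidence (population-genetic, homology, translation,
expression) to prioritise them.

## The method in brief

1. **Scan & classify.** Spliced transcripts are scanned for ORFs (most
   upstream AUG per stop codon, >= 9 codons); identical ORFs across
   isoforms are grouped and classified (`annotated`, `pseudogene`,
   `ncRNA`, `utr3`, `utr5`, `cds_overlap`, `other`, `lincRNA`).
2. **Conservation features.** Per ORF, from stitched alignment blocks: a
   codon-level selection score (precomputed phyloCSF-style scores, or a
   built-in surrogate `sum log2(P_cod(e)/P_nc(e))` over species-codon
   events e in {identical, synonymous, non-synonymous, stop}); the number
   of species with intact reading frame (coverage >= 50 %, no
   frameshifting indel); and Euclidean distances of the 50-nt
   start/stop conservation profiles from the positive-set mean.
3. **Classify & filter.** A linear SVM on the whitened features (trained
   on curated annotated small proteins vs. ncRNA ORFs; error rates from
   100 resampling runs) is followed by a two-pass overlap filter that
   removes predictions intersecting conserved coding exons or contained
   in longer clean predictions.
4. **Evidence.** SNP-based dN/dS with Nei-Gojobori-style site counting
   and reciprocal one-sided chi-squared tests; cross-species homology
   clustering with `PID_eff = PID * alignment_length / query_length`
   against the length-dependent cutoff `30 + 70 exp(-(l_q + l_s)/20)`
   and reciprocal-best-hit cluster joining; ancestral conservation
   (MRCA of species with intact start/stop/splice sites and frame);
   peptide usage/KL codon bias/motifs-in-disorder; ribosome-profiling
   ORFscore `log2(sum (F_i - Fbar)^2 / Fbar + 1)` with a KS dataset gate
   (D >= 0.55) and translation calls at score >= 6; TPM expression and
   information-content specificity; and 3'UTR-sORF (dORF) diagnostics
   against readthrough/alternative-exon explanations.

A synthetic-data generator (`simulateLocusSet()`) emulates every input
format (FASTA, GTF, MAF, bedGraph, VCF, BED, FPKM tables) with known
ground truth, so the whole pipeline is testable without external data.

## Worked example

```r
library(sorfcons)
library(Biostrings)

cfg <- simulationConfig(seed = 1L, n_coding = 40, n_neutral = 40, n_pseudo = 5)
bundle <- simulateLocusSet(cfg, "fixtures")

txset <- readAnnotation(bundle$paths[["gtf"]])
genome <- readDNAStringSet(bundle$paths[["genome"]])
names(genome) <- sub(" .*", "", names(genome))
orfs <- classifyOrfs(buildOrfCatalog(txset, genome), txset)
orfs
#> ORFSet with 123 ORF group(s)
#>   codons: 9-60
#>   categories: annotated(20) cds_overlap(2) lincRNA(30) ncRNA(59) other(4) pseudogene(8)

blocks <- readMaf(bundle$paths[["maf"]])
track  <- readConservationTrack(bundle$paths[["track"]])
fx <- orfFeatures(orfs, txset, blocks, track)
head(fx$features, 3)
#>     orf_id  score n_frame_species d_start d_stop
#> 1 orf00001 24.068               4       0      0
#> 2 orf00002 37.560               4       0      0
#> 3 orf00003 57.694               4       0      0
```

The catalog contains the 85 planted ORFs plus chance ORFs found in the
scanned transcripts. `score` is the codon-level selection score (positive
= coding-like substitution pattern; the first three ORFs are planted
coding-like loci), `n_frame_species` counts aligned species with an
intact reading frame, and `d_start`/`d_stop` measure how far the ORF's
boundary conservation profiles are from the positive-set mean (0 here
because the generator's noiseless track gives every coding-like locus the
same sharp step). Feeding these four columns to
`fitSvm()`/`crossValidate()` separates coding-like from neutral loci; see
the vignette (`vignettes/conserved-sorfs.Rmd`) for the full tour,
including dN/dS, clustering, ORFscore and dORF analyses.

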