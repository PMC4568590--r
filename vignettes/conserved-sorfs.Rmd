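---
title: "Finding conserved small ORFs: models, parameters and design choices"
author: "sorfcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding conserved small ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Short open reading frames (sORFs, here AUG-initiated ORFs of 9 to ~101
codons) occur by chance in any transcript, so length and composition alone
cannot distinguish the few that encode functional micropeptides from noise.
What does distinguish them is the signature of purifying selection acting on
the *peptide*: synonymous substitutions are tolerated, non-synonymous ones
depleted, frameshifting indels absent, and nucleotide-level conservation
drops sharply outside the ORF boundaries. `sorfcons` implements a pipeline
that extracts these signatures from multiple-species alignments and
conservation tracks, combines them in a linear support-vector machine, and
follows up predicted sORFs with population-genetic, homology, translation
and expression evidence.

# Pipeline and models

## ORF scanning and classification

Each spliced transcript is scanned for ORFs with the *most upstream AUG per
stop codon* rule: for every in-frame stop there is at most one candidate,
beginning at the first AUG after the previous in-frame stop. The minimum
span is 27 nt including the stop codon, i.e. nine codons encoding eight
amino acids; this convention is configurable (`min_nt`). ORFs truncated by
the transcript end and ORFs with an ambiguous base in any codon are
discarded. Unstranded transcript models are scanned on both strands.

ORFs identical in genomic coordinates and peptide across isoforms form one
group, classified by the first matching rule in a fixed order: `annotated`
(exact match to the CDS of a protein-coding transcript, with or without the
stop codon, since common annotation conventions exclude it), `pseudogene`,
`ncRNA` (miRNA/rRNA/tRNA/snRNA/snoRNA — the negative-control pool),
`utr3`/`utr5` (inside a UTR with zero overlap with the CDS reference),
`cds_overlap`, `other`, `lincRNA`. A final pass moves groups fully
contained in annotated CDS into `cds_overlap` unless the group is `other`.
The pseudogene test accepts either a transcript or a gene-level pseudogene
biotype. Duplicate exon chains across annotation catalogs are deduplicated
(reference catalog wins) — merging rules across catalogs are rarely
specified, and identical chains carry no extra information.

## Conservation features

Four features feed the classifier, computed per ORF from alignment blocks
restricted to the ORF ("stitched" in transcript orientation):

1. **Selection score.** Production use plugs in precomputed codon-level
   likelihood scores (e.g. phyloCSF) via the `table` backend. The built-in
   `surrogate` backend sums, over qualifying species (coverage >= 50 %, no
   frameshifting indel) and gap-free codon columns,
   `log2(P_cod(event) / P_nc(event))`, classifying each species codon
   against the reference as identical, synonymous, non-synonymous or
   stop-introducing. The default tables `P_cod = (0.55, 0.30, 0.14, 0.01)`
   and `P_nc = (0.40, 0.20, 0.35, 0.05)` are package defaults chosen so
   that coding-like and neutrally evolving fixtures separate; they are not
   fitted to any particular clade and are fully configurable. Events are
   classified against the reference codon directly, without ancestral
   reconstruction — the pairwise spirit matches the other features and
   keeps the score exact on fixtures.
2. **Frame conservation count**: species with >= 50 % coverage and no
   frameshifting indel (computed on the raw blocks via the insertion index,
   before stitching). Coverage counts aligned non-gap reference positions;
   gaps inside covered blocks count against coverage.
3. & 4. **Boundary step profiles**: per-base conservation in 50-nt windows
   at the start (25 nt upstream + first 25 nt) and stop (last 25 nt +
   25 nt downstream), introns excluded, extended into flanking genomic
   sequence where needed. The features are Euclidean distances from the
   base-wise mean profile of the positive training set. Windows clipped at
   a contig edge are rescaled by `sqrt(50 / observed)` so distances stay
   comparable.

## Classifier

Features are whitened to zero mean and unit variance (population sd, so the
model is exactly invariant under duplicating the training data; a constant
feature gets scale 1 with a warning) and a linear SVM is fitted with cost
C = 1 — the cost is a package default, configurable, as linear SVMs on four
well-separated features are insensitive to it. Positives are curated
annotated sORFs of at most 101 codons with alignment coverage and positive
selection score, minus a user-supplied exclusion list of fast-evolving
peptides; negatives are `ncRNA` sORFs with coverage and no CDS overlap.
Error rates come from 100 resampling runs (each example joins the training
half with probability 0.5; prediction on the rest); a run with an empty
held-out class is redrawn and logged. Score cutoffs are chosen at the
minimum-average-error point of the ROC curve, scanning midpoints of sorted
unique scores plus the scores themselves, ties resolved towards the
smallest threshold.

## Overlap filter

Pass 1 keeps annotated sORFs and any sORF not intersecting (>= 1 bp, both
strands by default, configurable) a conserved coding exon — exons whose
frame-conservation count reaches a threshold chosen like the ROC cutoff
above. Pass 2 removes predictions strictly contained (same strand, genomic
chain containment — containment across transcripts is a genomic notion
here) in a longer prediction that itself is exon-clean; the family
representative is the longest ORF, ties broken by the better selection
score. The filter is idempotent and leaves no contained pairs.

## Selection analyses

Length-adjusted scores are z-scores within length-percentile bins (100
bins; bins under 20 members merge with the nearest neighbour; population
sd; all-equal bins give z = 0). Conservation-matched controls are drawn
from the 20 % of the pool closest to zero score, stratified on deciles of
mean per-base conservation, until a Wilcoxon rank test against the
candidates gives P > 0.1 (or a 1,000-attempt budget errors out reporting
the best P achieved).

SNP-based dN/dS uses equal-weight (Nei–Gojobori-style) site counting —
each codon contributes `#synonymous single-nt changes / 3` synonymous
sites, the remaining 3 − s non-synonymous; changes to stop count as
non-synonymous. Start and stop codons are excluded from both sites and SNP
counts. SNPs on the minus strand, in masked repeats, or with derived allele
frequency below 1 % are removed first; multi-allelic records are split into
biallelic ones. `dN/dS = (nN / n_sites) / (nS / s_sites)`; `nS = 0` yields
`Inf` with an explicit flag. The "reciprocal" chi-squared test is defined
here as a one-sided goodness-of-fit test of the observed
(non-synonymous, synonymous) counts against the site-proportion
expectation, run for candidates and controls separately, reporting both P
values and their maximum — the construction is stated explicitly because
contingency conventions differ between tools.

## Homology clustering

Directed hits qualify when the peptides differ in length by at most 20 %
(relative to the longer), E < 10, and
`PID_eff = PID x alignment length / query length` exceeds
`30 + 70 exp(-(len_q + len_s)/20)` — each directed hit is tested with its
own query length. Non-reciprocal edges are dropped; within-species
connected components form paralog clusters; between species only
reciprocal-best cluster pairs connect (best = maximal `PID_eff` over member
pairs, ties by lower E-value then lexicographic id — the cluster-level
score had to be fixed here). Singletons are removed. Isomorphic clusters
(species + category as vertex colours, canonical via BLISS) collapse into
representatives with multiplicities; the standard report keeps clusters
with >= 2 species and >= 1 non-annotated member. A Smith–Waterman aligner
(PAM30, gap open 9 / extend 1, small-database Karlin–Altschul E-value
approximation with lambda = 0.32, K = 0.14) generates hit tables for
fixtures; real analyses consume external tabular hits.

## Translation, expression, dORFs

ORFscore: with per-frame 5'-end counts `F` over the ORF (first and last
codon excluded — initiation and termination pile-ups distort the frame
signal; configurable upstream) and mean `Fbar`, the score is
`log2(sum (F_i - Fbar)^2 / Fbar + 1)`, negated when frame 2 or 3 dominates.
Reads arrive as offset-corrected 5'-end BED; `metageneOffsets()` estimates
per-read-length offsets from annotated CDS starts, pooling all samples
before estimation, choosing the offset maximising the frame-1 fraction
with ties broken by the initiation-peak position then the smaller offset.
Datasets must separate annotated from negative-control ORFscores with a
Kolmogorov–Smirnov D >= 0.55; translation is called at score >= 6.

Expression: transcripts with all FPKM below 1e-4 are dropped; TPM columns
each sum to 1e6; mean expression averages non-zero TPM; specificity is the
normalised information content of `r_t = log2(TPM_t + 1) / sum_s
log2(TPM_s + 1)` (0 = uniform, 1 = single sample).

dORF diagnostics measure, in spliced transcript coordinates, the
conservation step at the host CDS stop (25 nt inside vs. 25 nt outside,
the stop codon itself in neither window — the symmetric-exclusion
convention, configurable), the distance and reading-frame offset of the
dORF start relative to the CDS, intervening in-frame stops, and overlap
with annotated CDS of other isoforms. Readthrough candidates match on
exact genomic stop-codon coordinates. External catalogs match on stop
coordinates, exact peptide equality, or tryptic-peptide substrings
requiring a preceding K/R — with N-terminal peptides accepted with or
without the initiator methionine, the usual mass-spectrometry convention.

# The synthetic-data generator

`simulateLocusSet()` produces every input format with ground truth. Each
locus is a single-exon, plus-strand transcript (60-nt UTRs free of AUG so
the planted ORF keeps the most-upstream-AUG property, 15–60-codon ORF,
100-nt genomic pad). Three classes:

- **coding-like** (default 200): codon substitution along the 5-species
  tree `((((ref,spA),spB),spC),spD)` with synonymous rate 1.2 and
  non-synonymous rate 0.12 per codon per unit branch (single-nucleotide
  codon neighbours, no rate heterogeneity across sites — enough structure
  to exercise the features without a full codon model), rare in-frame
  deletions, UTRs evolving neutrally, and a conservation-track step
  (0.2 outside / 0.9 inside the ORF). Half are annotated as
  protein-coding (CDS written, the positive-control pool), half as
  lincRNA.
- **neutral** (default 200): frame-agnostic substitution at 0.5/nt/unit,
  indels at 0.01/nt/unit with lengths 1–3 (mostly frameshifting), flat
  track, `snoRNA` biotype (the negative-control pool).
- **pseudogene-like** (default 20): intact reference ORF, neutrally
  evolving alignment, flat track, pseudogene biotype.

SNPs are planted with a *known* dN/dS: all single-nucleotide changes of
interior codons are enumerated, and the realised synonymous and
non-synonymous counts are fixed at their expectations under weights
1 : omega (positions random, density 20/kb over interior coding
nucleotides). Flagged fractions (2 % each rare, in-repeat, minus-strand)
are stratified by class so the post-filter truth still equals omega —
randomness then probes the estimator's position mapping, allele
orientation and classification, not sampling noise in the planted signal.
Ribosome 5' ends use an 80 % frame-1 bias (coding) or uniform positions
(neutral) at a Poisson mean of 150 reads per ORF, a depth at which the
ORFscore cutoff of 6 is informative. Expression profiles alternate
single-sample-specific and broad across 8 samples. Twenty peptide families
(20–35 aa, up to 2 substitutions per species copy, 3 species) plus random
background peptides drive the clustering tests.

What the generator does *not* emulate: multi-exon and minus-strand gene
structures (exercised by hand-built fixtures in the unit tests instead),
alignment-coverage gaps, overlapping genes, paralogous loci, sequencing
noise in expression values, and any realistic base composition. Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted signals, not performance on real genomes.

# Problem sizes and numerical conventions

The standard test conditions are 200 coding-like + 200 neutral loci for
classifier evaluation (100 resampling runs), ~10 kb of coding sequence and
50 replicates for dN/dS recovery, 1,000 random sequences (100–5,000 nt)
for the scanner-oracle equivalence, 500 randomized prediction sets for the
overlap-filter properties, and 20 planted families for clustering. All
randomness flows from a single seed per run. Internally all coordinates
are 1-based inclusive `GRanges`; 0-based external formats (BED, bedGraph,
MAF) are converted on read and write, so exactly one convention exists on
each side of an interface. Conservation-track positions absent from the
input read as 0. Ties and degenerate inputs are resolved as documented on
each function (e.g. z = 0 in constant score bins, score 0 for alignments
with no qualifying species, redrawn resampling runs).

# Worked example

```{r example, eval = FALSE}
library(sorfcons)
library(Biostrings)

cfg <- simulationConfig(seed = 1L, n_coding = 40, n_neutral = 40, n_pseudo = 5)
bundle <- simulateLocusSet(cfg, "fixtures")

txset <- readAnnotation(bundle$paths[["gtf"]])
genome <- readDNAStringSet(bundle$paths[["genome"]])
names(genome) <- sub(" .*", "", names(genome))
orfs <- classifyOrfs(buildOrfCatalog(txset, genome), txset)

blocks <- readMaf(bundle$paths[["maf"]])
track <- readConservationTrack(bundle$paths[["track"]])
fx <- orfFeatures(orfs, txset, blocks, track)
head(fx$features)
```

# Known limitations

Non-AUG start codons are out of scope, as is codon-aware re-alignment of
weakly aligned candidates; the surrogate selection score is a fixture-grade
stand-in for a phylogenetic codon model and real analyses should supply
precomputed scores; the overlap filter is deliberately conservative and
will discard genuine sORFs overlapping longer ORFs in alternative frames;
and synteny confirmation of homology clusters requires external liftover
tooling.
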