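#' Configuration for the synthetic locus-set generator
#'
#' Bundles every tunable of [simulateLocusSet()]. Defaults define the
#' standard study conditions used throughout the test suite: 200
#' coding-like and 200 neutral loci, a 5-species tree, synonymous-biased
#' codon substitution for coding-like loci (synonymous rate 1.2,
#' non-synonymous 0.12 per codon per unit branch length), frame-agnostic
#' substitution with frequent short indels for neutral loci, SNP density
#' 20/kb with per-class true dN/dS, 80 % frame-1 read bias at 150 reads
#' per translated ORF, and a conservation-track step (0.2 outside /
#' 0.9 inside) only at coding-like ORFs.
#'
#' @param seed RNG seed; the full output bundle is a deterministic
#'   function of the config.
#' @param n_coding,n_neutral,n_pseudo loci per class.
#' @param orf_codons inclusive range of ORF lengths (codons, >= 9).
#' @param utr,pad UTR length (each side) and genomic pad beyond the
#'   transcript (nt).
#' @param tree Newick species tree with branch lengths; first tip is the
#'   reference.
#' @param syn_rate,nonsyn_rate coding-like codon substitution rates.
#' @param neutral_rate per-nucleotide substitution rate (UTRs and neutral
#'   loci).
#' @param indel3_rate in-frame (3-nt) deletion rate per ORF per unit
#'   branch (coding-like).
#' @param neutral_indel_rate indel events per nucleotide per unit branch
#'   (neutral/pseudogene), lengths uniform on 1..3.
#' @param snp_per_kb SNP density over ORF interiors.
#' @param omega_coding,omega_neutral true dN/dS per class.
#' @param rare_frac,repeat_frac,minus_frac fractions of SNPs flagged rare
#'   (DAF < 1 %), in-repeat, or minus-strand (all excluded by the dN/dS
#'   filters).
#' @param ribo_depth mean reads per ORF; `frame_bias` frame-1 probability
#'   for coding-like ORFs (neutral ORFs get uniform positions);
#'   `read_length` nominal read length.
#' @param n_samples expression samples; half the transcripts are
#'   single-sample specific, half broadly expressed.
#' @param track_low,track_high conservation-track levels.
#' @param n_families,family_species,family_len,n_background_peptides
#'   planted peptide homology families.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(seed = 1L, n_coding = 200L, n_neutral = 200L,
                             n_pseudo = 20L, orf_codons = c(15L, 60L),
                             utr = 60L, pad = 100L,
                             tree = "((((ref:0.10,spA:0.12):0.08,spB:0.20):0.12,spC:0.35):0.15,spD:0.60);",
                             syn_rate = 1.2, nonsyn_rate = 0.12,
                             neutral_rate = 0.5, indel3_rate = 0.02,
                             neutral_indel_rate = 0.01, snp_per_kb = 20,
                             omega_coding = 0.2, omega_neutral = 1.0,
                             rare_frac = 0.02, repeat_frac = 0.02,
                             minus_frac = 0.02, ribo_depth = 150,
                             frame_bias = 0.8, read_length = 29L,
                             n_samples = 8L, track_low = 0.2,
                             track_high = 0.9, n_families = 20L,
                             family_species = c("ref", "spA", "spB"),
                             family_len = c(20L, 35L),
                             n_background_peptides = 5L) {
  if (orf_codons[1L] < 9L)
    stop("infeasible config: ORFs must span at least 9 codons (27 nt)")
  if (frame_bias < 1 / 3 || frame_bias > 1)
    stop("frame_bias must lie in [1/3, 1]")
  rates <- c(syn_rate, nonsyn_rate, neutral_rate, indel3_rate,
             neutral_indel_rate, snp_per_kb, ribo_depth)
  if (any(rates < 0)) stop("rates must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

SENSE_CODONS <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- names(codon2aa())[codon2aa() != "*"]
    v
  }
})

## single-nucleotide codon neighbours, split by effect
codonNeighbours <- local({
  tabs <- NULL
  function() {
    if (!is.null(tabs)) return(tabs)
    gc <- codon2aa()
    syn <- nonsyn <- vector("list", length(gc))
    names(syn) <- names(nonsyn) <- names(gc)
    for (cod in names(gc)) {
      s <- n <- character(0)
      for (p in 1:3) for (nt in setdiff(NUCS, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- nt
        if (gc[[mut]] == "*") next
        if (gc[[mut]] == gc[[cod]]) s <- c(s, mut) else n <- c(n, mut)
      }
      syn[[cod]] <- s
      nonsyn[[cod]] <- n
    }
    tabs <<- list(syn = syn, nonsyn = nonsyn)
    tabs
  }
})

## every single-nucleotide change of every codon: 9 rows per codon
snpChangeTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- codon2aa()
    rows <- list()
    for (cod in names(gc)) {
      for (p in 1:3) for (nt in setdiff(NUCS, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- nt
        rows[[length(rows) + 1L]] <- data.frame(
          codon = cod, p = p, ref_base = substr(cod, p, p), alt = nt,
          syn = gc[[mut]] != "*" && gc[[mut]] == gc[[cod]],
          stringsAsFactors = FALSE)
      }
    }
    t2 <- do.call(rbind, rows)
    attr(t2, "rowsByCodon") <- split(seq_len(nrow(t2)), t2$codon)
    tab <<- t2
    tab
  }
})

randomDna <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

## random sequence free of ATG (for UTRs, so planted ORF starts stay
## the most upstream AUG for their stop)
randomUtr <- function(n) {
  s <- randomDna(n)
  while (grepl("ATG", s, fixed = TRUE))
    s <- sub("ATG", paste0("A", sample(c("CG", "AG", "TC", "GG"), 1L)), s, fixed = TRUE)
  s
}

randomOrf <- function(n_codons) {
  body <- sample(setdiff(SENSE_CODONS(), "ATG"), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

## ref-tip-outward traversal order of an ape tree: list of (from, to, length)
refOutwardEdges <- function(tree, ref) {
  nt <- length(tree$tip.label)
  refNode <- match(ref, tree$tip.label)
  adj <- rbind(data.frame(a = tree$edge[, 1L], b = tree$edge[, 2L],
                          len = tree$edge.length),
               data.frame(a = tree$edge[, 2L], b = tree$edge[, 1L],
                          len = tree$edge.length))
  visited <- refNode
  queue <- refNode
  out <- NULL
  while (length(queue)) {
    node <- queue[1L]; queue <- queue[-1L]
    nb <- adj[adj$a == node & !adj$b %in% visited, , drop = FALSE]
    for (k in seq_len(nrow(nb))) {
      out <- rbind(out, nb[k, ])
      visited <- c(visited, nb[k, "b"])
      queue <- c(queue, nb[k, "b"])
    }
  }
  out$a_label <- nodeLabel(tree, out$a)
  out$b_label <- nodeLabel(tree, out$b)
  out
}

nodeLabel <- function(tree, node) {
  nt <- length(tree$tip.label)
  ifelse(node <= nt, tree$tip.label[node], paste0("node", node))
}

## evolve one species state (chars aligned to ref, '-' = deleted;
## insertions as data.frame(pos, len) in transcript coordinates)
evolveBranch <- function(state, t, model, orfStart, orfEnd, cfg) {
  chars <- state$chars
  nb <- codonNeighbours()
  substitute <- function(idx, p) {
    alive <- idx[chars[idx] %in% NUCS]
    mut <- alive[stats::runif(length(alive)) < p]
    if (length(mut))
      chars[mut] <<- vapply(chars[mut],
                            function(b) sample(setdiff(NUCS, b), 1L), "")
  }
  if (model == "coding") {
    utrIdx <- setdiff(seq_along(chars), orfStart:orfEnd)
    substitute(utrIdx, 1 - exp(-cfg$neutral_rate * t))
    pS <- 1 - exp(-cfg$syn_rate * t)
    pN <- 1 - exp(-cfg$nonsyn_rate * t)
    codStarts <- seq(orfStart + 3L, orfEnd - 5L, by = 3L)  # interior codons
    for (cs in codStarts) {
      cod <- paste(chars[cs:(cs + 2L)], collapse = "")
      if (!cod %in% names(nb$syn)) next                    # gap or N
      if (stats::runif(1L) < pS && length(nb$syn[[cod]]))
        cod <- sample(nb$syn[[cod]], 1L)
      if (stats::runif(1L) < pN && length(nb$nonsyn[[cod]]))
        cod <- sample(nb$nonsyn[[cod]], 1L)
      chars[cs:(cs + 2L)] <- strsplit(cod, "")[[1L]]
    }
    if (stats::runif(1L) < 1 - exp(-cfg$indel3_rate * t) && length(codStarts)) {
      cs <- sample(codStarts, 1L)
      chars[cs:(cs + 2L)] <- "-"
    }
  } else {                                                 # neutral/pseudogene
    substitute(seq_along(chars), 1 - exp(-cfg$neutral_rate * t))
    alive <- which(chars %in% NUCS)
    nIndel <- stats::rpois(1L, cfg$neutral_indel_rate * t * length(alive))
    for (k in seq_len(nIndel)) {
      len <- sample(1:3, 1L)
      if (stats::runif(1L) < 0.5 && length(alive) > len + 1L) {
        at <- sample(seq_len(length(alive) - len), 1L)
        chars[alive[at:(at + len - 1L)]] <- "-"
        alive <- which(chars %in% NUCS)
      } else {
        state$ins <- rbind(state$ins,
                           data.frame(pos = sample(seq_along(chars), 1L),
                                      len = len))
      }
    }
  }
  state$chars <- chars
  state
}

#' Simulate SNPs with a known dN/dS over an ORF set
#'
#' Enumerates every single-nucleotide change of the interior codons
#' (start/stop excluded) of the given ORFs, classifies each as synonymous
#' or non-synonymous (stop-introducing counts as non-synonymous), and
#' places SNPs so that the realised synonymous : non-synonymous count
#' ratio matches the target `omega` exactly (counts fixed at their
#' expectations under weights 1 : omega; positions random). Fractions of
#' SNPs are flagged rare / in-repeat / minus-strand, stratified by class
#' so the post-filter dN/dS still equals `omega`.
#'
#' @param orfset an [ORFSet].
#' @param ids ORFs to cover (default: all).
#' @param omega target dN/dS.
#' @param snp_per_kb density over the interior coding nucleotides.
#' @param rare_frac,repeat_frac,minus_frac flagged fractions.
#' @return `GRanges` shaped like [readVariants()] output.
#' @export
simulateSnps <- function(orfset, omega, snp_per_kb = 20,
                         ids = orfIds(orfset), rare_frac = 0.02,
                         repeat_frac = 0.02, minus_frac = 0.02) {
  tab <- snpChangeTable()
  rowsByCodon <- attr(tab, "rowsByCodon")
  parts <- vector("list", length(ids))
  allIdx <- match(ids, orfIds(orfset))
  for (j in seq_along(ids)) {
    i <- allIdx[j]
    chain <- orfset@ranges[[i]]
    strand <- exonStrand(chain)
    pos <- txPositions(chain, strand)
    codons <- splitCodons(orfset@info$nt_seq[i])
    nc <- length(codons)
    inner <- seq(2L, nc - 1L)
    rows <- unlist(rowsByCodon[codons[inner]], use.names = FALSE)
    off <- rep((inner - 1L) * 3L, each = 9L) + tab$p[rows]
    rb <- tab$ref_base[rows]; ab <- tab$alt[rows]
    if (strand == "-") {
      rb <- chartr("ACGT", "TGCA", rb)
      ab <- chartr("ACGT", "TGCA", ab)
    }
    parts[[j]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(chain)[1L]),
      gpos = pos[off], ref = rb, alt = ab, syn = tab$syn[rows],
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, parts)
  chrom <- all$chrom; gpos <- all$gpos; ref <- all$ref; alt <- all$alt
  syn <- all$syn
  totalNt <- length(syn) / 9 * 3
  target <- snp_per_kb * totalNt / 1000
  wS <- sum(syn); wN <- omega * sum(!syn)
  nS <- round(target * wS / (wS + wN))
  nN <- round(target * wN / (wS + wN))
  key <- paste(chrom, gpos)
  pickClass <- function(mask, n) {
    cand <- which(mask)
    cand <- cand[!duplicated(key[cand])]
    sample(cand, min(n, length(cand)))
  }
  iS <- pickClass(syn, nS)
  iN <- pickClass(!syn & !key %in% key[iS], nN)
  sel <- c(iS, iN)
  isSyn <- c(rep(TRUE, length(iS)), rep(FALSE, length(iN)))
  flag <- function(frac) {
    f <- logical(length(sel))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(isSyn == cls)
      k <- round(frac * length(idx))
      if (k > 0L) f[sample(idx, k)] <- TRUE
    }
    f
  }
  rare <- flag(rare_frac)
  inrep <- flag(repeat_frac) & !rare
  minus <- flag(minus_frac) & !rare & !inrep
  daf <- stats::runif(length(sel), 0.01, 0.5)
  daf[rare] <- stats::runif(sum(rare), 0.001, 0.009)
  gr <- GenomicRanges::GRanges(chrom[sel], IRanges::IRanges(gpos[sel], gpos[sel]))
  S4Vectors::mcols(gr) <- DataFrame(ref = ref[sel], alt = alt[sel], daf = daf,
                                    snp_strand = ifelse(minus, "-", "+"),
                                    in_repeat = inrep)
  GenomicRanges::sort(gr)
}

#' Simulate ribosome-profiling 5' ends for ORFs
#'
#' Coding-like ORFs get reads at codon starts of their interior codons
#' with frame probabilities `(bias, (1-bias)/2, (1-bias)/2)`; a bias of
#' 1/3 gives uniform positions (the neutral condition).
#'
#' @param orfset an [ORFSet].
#' @param ids ORFs to cover.
#' @param bias frame-1 probability in `[1/3, 1]`.
#' @param depth mean (Poisson) reads per ORF.
#' @param read_length reported read length.
#' @return data.frame `chrom`, `pos`, `strand`, `length` of read 5' ends.
#' @export
simulateRiboReads <- function(orfset, ids = orfIds(orfset), bias = 0.8,
                              depth = 150, read_length = 29L) {
  rows <- list()
  for (id in ids) {
    i <- match(id, orfIds(orfset))
    chain <- orfset@ranges[[i]]
    strand <- exonStrand(chain)
    pos <- txPositions(chain, strand)
    n <- stats::rpois(1L, depth)
    if (n == 0L) next
    inner <- seq(4L, length(pos) - 3L)       # exclude start & stop codons
    frame <- sample(1:3, n, replace = TRUE,
                    prob = c(bias, (1 - bias) / 2, (1 - bias) / 2))
    codon <- sample(seq(0L, length(inner) / 3L - 1L), n, replace = TRUE)
    off <- inner[codon * 3L + frame]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(chain)[1L]),
      pos = pos[off], strand = strand, length = read_length,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               length = integer(0))
}

#' Generate a complete synthetic input bundle
#'
#' Produces, under `out_dir`, every input the pipeline consumes with known
#' ground truth: `genome.fa`, `annotation.gtf`, `alignment.maf`,
#' `conservation.bedGraph`, `snps.vcf`, `ribo_reads.bed`, `fpkm.tsv`,
#' `peptides.tsv`, `tree.nwk` and `truth_loci.tsv`. Each locus is a
#' single-exon plus-strand transcript (UTR - ORF - UTR) on its own
#' chromosome. Coding-like loci evolve with synonymous-biased codon
#' substitution, conserved frame and a conservation step over the ORF;
#' neutral loci evolve frame-agnostically with frequent frameshifting
#' indels and a flat track; pseudogene-like loci carry an intact
#' reference ORF but neutrally evolving alignments and a flat track.
#' Given the same config the bundle is byte-identical across runs.
#'
#' @param config a [simulationConfig()].
#' @param out_dir output directory (created).
#' @return invisible list with `paths` (named file paths), `truth` (locus
#'   table), `peptides`, `orfset` (the planted [ORFSet]) and `config`.
#' @export
simulateLocusSet <- function(config, out_dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  tree <- ape::read.tree(text = cfg$tree)
  refSp <- "ref"
  edges <- refOutwardEdges(tree, refSp)
  tips <- tree$tip.label

  classes <- c(rep("coding_like", cfg$n_coding), rep("neutral", cfg$n_neutral),
               rep("pseudogene", cfg$n_pseudo))
  n <- length(classes)
  truth <- vector("list", n)
  fa <- character(0)
  gtf <- character(0)
  mafBlocks <- list()
  bg <- list()
  chainsList <- vector("list", n)
  ntList <- character(n)

  for (i in seq_len(n)) {
    cls <- classes[i]
    chrom <- sprintf("L%04d", i)
    nc <- sample(seq(cfg$orf_codons[1L], cfg$orf_codons[2L]), 1L)
    orfSeq <- randomOrf(nc)
    txSeq <- paste0(randomUtr(cfg$utr), orfSeq, randomUtr(cfg$utr))
    txLen <- nchar(txSeq)
    chromSeq <- paste0(randomDna(cfg$pad), txSeq, randomDna(cfg$pad))
    fa <- c(fa, paste0(">", chrom), chromSeq)
    exonStart <- cfg$pad + 1L
    exonEnd <- cfg$pad + txLen
    orfTxStart <- cfg$utr + 1L
    orfTxEnd <- cfg$utr + 3L * nc
    biotype <- switch(cls,
      coding_like = if (i %% 2L == 0L) "protein_coding" else "lincRNA",
      neutral = "snoRNA",
      pseudogene = "processed_pseudogene")
    txId <- sprintf("TX%04d", i)
    geneId <- sprintf("G%04d", i)
    attr1 <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                            'gene_biotype "%s"; transcript_biotype "%s";'),
                     geneId, txId, biotype, biotype)
    gtf <- c(gtf, sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\t%s",
                          chrom, exonStart, exonEnd, attr1))
    if (biotype == "protein_coding") {
      ## CDS excludes the stop codon (annotation convention)
      gtf <- c(gtf, sprintf("%s\tsim\tCDS\t%d\t%d\t.\t+\t0\t%s",
                            chrom, cfg$pad + orfTxStart,
                            cfg$pad + orfTxEnd - 3L, attr1))
    }
    ## evolve species rows over the transcript region
    model <- if (cls == "coding_like") "coding" else "neutral"
    states <- list()
    states[[refSp]] <- list(chars = strsplit(txSeq, "")[[1L]],
                            ins = data.frame(pos = integer(0), len = integer(0)))
    for (k in seq_len(nrow(edges))) {
      from <- edges$a_label[k]; to <- edges$b_label[k]
      states[[to]] <- evolveBranch(states[[from]], edges$len[k], model,
                                   orfTxStart, orfTxEnd, cfg)
    }
    rows <- c(stats::setNames(txSeq, refSp),
              vapply(tips[tips != refSp], function(sp)
                paste(states[[sp]]$chars, collapse = ""), character(1)))
    ins <- lapply(tips[tips != refSp], function(sp) {
      d <- states[[sp]]$ins
      if (nrow(d)) data.frame(pos = d$pos + cfg$pad, len = d$len) else NULL
    })
    names(ins) <- tips[tips != refSp]
    ins <- Filter(Negate(is.null), ins)
    mafBlocks[[i]] <- list(chrom = chrom, start = exonStart, end = exonEnd,
                           ref = refSp, rows = rows, ins = ins)
    ## conservation track
    step <- cls == "coding_like"
    gOrfStart <- cfg$pad + orfTxStart
    gOrfEnd <- cfg$pad + orfTxEnd
    bg[[i]] <- if (step) data.frame(
      chrom = chrom,
      start = c(1L, gOrfStart, gOrfEnd + 1L),
      end = c(gOrfStart - 1L, gOrfEnd, nchar(chromSeq)),
      score = c(cfg$track_low, cfg$track_high, cfg$track_low)) else
      data.frame(chrom = chrom, start = 1L, end = nchar(chromSeq),
                 score = cfg$track_low)
    chainsList[[i]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(gOrfStart, gOrfEnd), strand = "+")
    ntList[i] <- orfSeq
    truth[[i]] <- data.frame(
      locus = chrom, tx_id = txId, class = cls, biotype = biotype,
      n_codons = nc, orf_tx_start = orfTxStart, orf_tx_end = orfTxEnd,
      omega = if (cls == "coding_like") cfg$omega_coding else cfg$omega_neutral,
      frame_bias = if (cls == "coding_like") cfg$frame_bias else 1 / 3,
      expr_class = if (i %% 2L == 0L) "specific" else "broad",
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  ## planted ORF set (drives SNP/read simulation and truth matching)
  planted <- plantedOrfSet(truth, chainsList, ntList)

  ## SNPs per class with the class's true omega
  vC <- if (any(truth$class == "coding_like"))
    simulateSnps(planted, cfg$omega_coding, cfg$snp_per_kb,
                 ids = planted@info$orf_id[truth$class == "coding_like"],
                 rare_frac = cfg$rare_frac, repeat_frac = cfg$repeat_frac,
                 minus_frac = cfg$minus_frac) else NULL
  vN <- if (any(truth$class != "coding_like"))
    simulateSnps(planted, cfg$omega_neutral, cfg$snp_per_kb,
                 ids = planted@info$orf_id[truth$class != "coding_like"],
                 rare_frac = cfg$rare_frac, repeat_frac = cfg$repeat_frac,
                 minus_frac = cfg$minus_frac) else NULL
  variants <- if (is.null(vC)) vN else if (is.null(vN)) vC else
    GenomicRanges::sort(suppressWarnings(c(vC, vN)))

  ## ribosome reads: biased for coding-like, uniform for neutral
  readsC <- simulateRiboReads(planted,
    ids = planted@info$orf_id[truth$class == "coding_like"],
    bias = cfg$frame_bias, depth = cfg$ribo_depth,
    read_length = cfg$read_length)
  readsN <- simulateRiboReads(planted,
    ids = planted@info$orf_id[truth$class == "neutral"],
    bias = 1 / 3, depth = cfg$ribo_depth, read_length = cfg$read_length)
  reads <- rbind(readsC, readsN)

  ## expression matrix
  fpkm <- matrix(0, nrow = n, ncol = cfg$n_samples,
                 dimnames = list(truth$tx_id,
                                 sprintf("sample_%02d", seq_len(cfg$n_samples))))
  for (i in seq_len(n)) {
    if (truth$expr_class[i] == "specific") {
      fpkm[i, sample(cfg$n_samples, 1L)] <- 50 * stats::runif(1L, 0.5, 1.5)
    } else {
      fpkm[i, ] <- 10 * stats::runif(cfg$n_samples, 0.5, 1.5)
    }
  }

  ## planted peptide homology families
  peptides <- simulateFamilies(cfg)

  paths <- c(genome = file.path(out_dir, "genome.fa"),
             gtf = file.path(out_dir, "annotation.gtf"),
             maf = file.path(out_dir, "alignment.maf"),
             track = file.path(out_dir, "conservation.bedGraph"),
             vcf = file.path(out_dir, "snps.vcf"),
             reads = file.path(out_dir, "ribo_reads.bed"),
             fpkm = file.path(out_dir, "fpkm.tsv"),
             peptides = file.path(out_dir, "peptides.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             truth = file.path(out_dir, "truth_loci.tsv"))
  writeLines(fa, paths["genome"])
  writeLines(gtf, paths["gtf"])
  writeMaf(mafBlocks, paths["maf"])
  bgAll <- do.call(rbind, bg)
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%g", bgAll$chrom, bgAll$start - 1L,
                       bgAll$end, bgAll$score)), paths["track"])
  writeSnpVcf(variants, paths["vcf"])
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$chrom, reads$pos - 1L,
                     reads$pos, paste0("len", reads$length), reads$strand),
             paths["reads"])
  utils::write.table(data.frame(tx_id = rownames(fpkm), fpkm,
                                check.names = FALSE),
                     paths["fpkm"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(peptides, paths["peptides"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(cfg$tree, paths["tree"])
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth = truth, peptides = peptides,
                 orfset = planted, config = cfg))
}

plantedOrfSet <- function(truth, chains, nts) {
  ids <- sprintf("planted_%s", truth$locus)
  rng <- GenomicRanges::GRangesList(chains)
  names(rng) <- ids
  aa <- vapply(nts, function(s) {
    cod <- splitCodons(s)
    paste(translateCodons(cod[-length(cod)]), collapse = "")
  }, character(1))
  info <- DataFrame(orf_id = ids,
                    tx_ids = IRanges::CharacterList(as.list(truth$tx_id)),
                    rep_tx = truth$tx_id,
                    tx_start = truth$orf_tx_start, tx_end = truth$orf_tx_end,
                    scan_strand = rep("+", nrow(truth)),
                    n_codons = truth$n_codons, nt_seq = unname(nts),
                    aa_seq = unname(aa), category = rep(NA_character_, nrow(truth)),
                    uses_most_upstream_aug = rep(TRUE, nrow(truth)))
  rownames(info) <- ids
  new("ORFSet", ranges = rng, info = info)
}

writeSnpVcf <- function(gr, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=DAF,Number=1,Type=Float,Description="Derived allele frequency">',
           '##INFO=<ID=STRAND,Number=1,Type=String,Description="Annotation strand">',
           '##INFO=<ID=REPEAT,Number=0,Type=Flag,Description="Falls into a masked repeat">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), gr$ref, gr$alt,
                  paste0("DAF=", signif(gr$daf, 4), ";STRAND=", gr$snp_strand,
                         ifelse(gr$in_repeat, ";REPEAT", "")))
  writeLines(c(hdr, body), path)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

## no local alignment between the candidate peptides and the accepted pool
## comes close to an accepted graph edge (the planted-dissimilarity
## condition: between-family similarity stays below the dynamic cutoff)
dissimilarFromPool <- function(candidates, pool, margin = 2) {
  if (length(pool) == 0L) return(TRUE)
  q <- stats::setNames(Biostrings::AAStringSet(candidates),
                       sprintf("c%03d", seq_along(candidates)))
  s <- stats::setNames(Biostrings::AAStringSet(pool),
                       sprintf("p%03d", seq_along(pool)))
  ok <- function(h) {
    pe <- pidEff(h$percent_identity, h$alignment_length, h$query_length)
    all(pe <= dynamicCutoff(h$query_length, h$subject_length) - margin)
  }
  ok(alignPeptides(q, s)) && ok(alignPeptides(s, q))
}

simulateFamilies <- function(cfg) {
  rows <- list()
  pool <- character(0)
  deriveCopy <- function(proto) {
    len <- nchar(proto)
    pep <- strsplit(proto, "")[[1L]]
    nm <- min(2L, len - 1L)
    at <- sample(len, nm)
    pep[at] <- sample(AA20, nm, replace = TRUE)
    paste(pep, collapse = "")
  }
  for (f in seq_len(cfg$n_families)) {
    copies <- NULL
    for (try in 1:100) {
      len <- sample(seq(cfg$family_len[1L], cfg$family_len[2L]), 1L)
      proto <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      cand <- vapply(cfg$family_species, function(sp) deriveCopy(proto),
                     character(1))
      if (dissimilarFromPool(cand, pool)) { copies <- cand; break }
    }
    if (is.null(copies)) stop("could not draw a dissimilar peptide family")
    pool <- c(pool, copies)
    for (si in seq_along(cfg$family_species)) {
      sp <- cfg$family_species[si]
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("fam%02d_%s", f, sp), species = sp,
        category = if (sp == "ref") "lincRNA" else "annotated",
        family = sprintf("fam%02d", f),
        aa_seq = copies[si], stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(cfg$n_background_peptides)) {
    for (sp in cfg$family_species) {
      bg <- NULL
      for (try in 1:100) {
        len <- sample(seq(cfg$family_len[1L], cfg$family_len[2L]), 1L)
        cand <- paste(sample(AA20, len, replace = TRUE), collapse = "")
        if (dissimilarFromPool(cand, pool)) { bg <- cand; break }
      }
      if (is.null(bg)) stop("could not draw a dissimilar background peptide")
      pool <- c(pool, bg)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("bg%02d_%s", b, sp), species = sp,
        category = "lincRNA", family = NA_character_,
        aa_seq = bg, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read ribosome-profiling 5' ends from BED
#'
#' @param path BED file of read 5' ends (name field `len<readlength>`).
#' @return data.frame `chrom`, `pos` (1-based), `strand`, `length`.
#' @export
readRiboBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  len <- suppressWarnings(as.integer(sub("^len", "", gr$name)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             length = len, stringsAsFactors = FALSE)
}
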