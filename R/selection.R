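#' Length-adjusted selection scores
#'
#' Converts raw selection scores to z-scores within length-percentile bins:
#' ORFs are binned by `n_bins` quantiles of the length distribution, bins
#' with fewer than `min_bin` members are merged with their nearest
#' neighbour, and within each bin `z = (x - mean) / sd` (population sd;
#' an all-equal bin gives z = 0).
#'
#' @param scores numeric vector of selection scores.
#' @param lengths ORF lengths (codons), parallel to `scores`.
#' @param n_bins number of percentile bins.
#' @param min_bin minimum bin occupancy before merging.
#' @return numeric vector of adjusted scores.
#' @export
adjustedScores <- function(scores, lengths, n_bins = 100L, min_bin = 20L) {
  stopifnot(length(scores) == length(lengths))
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  br <- unique(stats::quantile(lengths, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) <= 2L) rep(1L, n) else
    as.integer(cut(lengths, breaks = br, include.lowest = TRUE))
  ## merge thin bins with the nearest (preceding, else following) neighbour
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < min_bin]
    if (length(small) == 0L || length(tab) == 1L) break
    b <- as.integer(small[1L])
    others <- setdiff(as.integer(names(tab)), b)
    target <- others[which.min(abs(others - b))]
    bin[bin == b] <- target
  }
  z <- numeric(n)
  for (b in unique(bin)) {
    i <- bin == b
    s <- popSd(scores[i])
    z[i] <- if (s == 0) 0 else (scores[i] - mean(scores[i])) / s
  }
  z
}

#' Conservation-matched control ORFs
#'
#' From a pool of non-annotated, CDS-free ORFs, restricts to those whose
#' selection scores are among the 20 % closest to zero, then samples
#' stratified on deciles of mean per-base conservation until a two-sample
#' rank test between candidate and control mean conservation is
#' non-significant (P > `p_min`), or `max_attempts` is reached.
#'
#' @param cand_cons,pool_cons named numeric vectors of mean per-base
#'   conservation for candidates and pool ORFs.
#' @param pool_scores named numeric selection scores of the pool.
#' @param seed RNG seed.
#' @param p_min rank-test acceptance level.
#' @param max_attempts resampling budget.
#' @param score_quantile fraction of the pool (by |score|) eligible.
#' @return character vector of selected control ids (with attributes
#'   `p_value` and `attempts`).
#' @export
selectMatchedControls <- function(cand_cons, pool_cons, pool_scores, seed = 1L,
                                  p_min = 0.1, max_attempts = 1000L,
                                  score_quantile = 0.2) {
  stopifnot(!is.null(names(pool_cons)), !is.null(names(pool_scores)))
  elig <- names(pool_scores)[abs(pool_scores) <=
            stats::quantile(abs(pool_scores), score_quantile)]
  pool <- pool_cons[elig]
  if (length(pool) == 0L) stop("no pool ORFs within the score window")
  br <- unique(stats::quantile(cand_cons, probs = seq(0, 1, 0.1)))
  strat <- function(x) {
    if (length(br) <= 2L) rep(1L, length(x)) else
      as.integer(cut(x, breaks = c(-Inf, br[-c(1L, length(br))], Inf)))
  }
  candBin <- strat(cand_cons)
  poolBin <- strat(pool)
  need <- table(factor(candBin, levels = sort(unique(c(candBin, poolBin)))))
  set.seed(seed)
  best <- 0
  for (att in seq_len(max_attempts)) {
    pick <- character(0)
    for (b in names(need)) {
      if (need[[b]] == 0L) next
      avail <- names(pool)[poolBin == as.integer(b)]
      if (length(avail) == 0L) avail <- names(pool)
      pick <- c(pick, sample(avail, min(need[[b]], length(avail)),
                             replace = length(avail) < need[[b]]))
    }
    pick <- unique(pick)
    if (length(pick) < 2L) next
    p <- suppressWarnings(
      stats::wilcox.test(cand_cons, pool[pick])$p.value)
    best <- max(best, p)
    if (!is.na(p) && p > p_min) {
      attr(pick, "p_value") <- p
      attr(pick, "attempts") <- att
      return(pick)
    }
  }
  stop(sprintf("conservation matching infeasible: best rank-test P = %.3g after %d attempts",
               best, max_attempts))
}

## fraction of the 9 single-nucleotide changes of each codon that are
## synonymous (equal-weight site counting); returns s_sites, n_sites
NUCS <- c("A", "C", "G", "T")

#' Synonymous and non-synonymous site counts of codons
#'
#' Equal-weight (Nei-Gojobori-style) counting: each codon contributes
#' `s = (#synonymous single-nt changes) / 3` synonymous sites and
#' `n = 3 - s` non-synonymous sites; changes to a stop codon count as
#' non-synonymous.
#'
#' @param codons character vector of codons.
#' @return data.frame with `s_sites` and `n_sites` per codon.
#' @export
codonSites <- function(codons) {
  tab <- codonSiteTable()
  bad <- !codons %in% rownames(tab)
  if (any(bad)) stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  data.frame(s_sites = tab[codons, "s"], n_sites = tab[codons, "n"],
             row.names = NULL)
}

codonSiteTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- codon2aa()
    codons <- names(gc)
    s <- vapply(codons, function(cod) {
      aa <- gc[[cod]]
      syn <- 0L
      for (p in 1:3) for (nt in setdiff(NUCS, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- nt
        if (gc[[mut]] != "*" && gc[[mut]] == aa) syn <- syn + 1L
      }
      syn / 3
    }, numeric(1))
    tab <<- cbind(s = s, n = 3 - s)
    rownames(tab) <- codons
    tab
  }
})

#' SNP-based dN/dS of a set of ORFs
#'
#' Classifies SNPs falling into the ORFs' codons as synonymous or
#' non-synonymous against the reference codon, counts
#' synonymous/non-synonymous sites per codon ([codonSites()]), aggregates
#' over the set, and reports `dN/dS = (nN / n_sites) / (nS / s_sites)`.
#' Start and stop codons are excluded from both SNP and site counting.
#' SNP filters applied beforehand: minus-strand SNPs, SNPs in masked
#' repeats, and rare SNPs with derived allele frequency below `min_daf`
#' (SNPs without a DAF annotation are kept).
#'
#' @param orfset an [ORFSet].
#' @param ids ORF ids to aggregate (default: all).
#' @param variants `GRanges` from [readVariants()].
#' @param min_daf derived-allele-frequency threshold.
#' @return list with `n_syn`, `n_nonsyn`, `s_sites`, `n_sites`, `dnds`
#'   (`Inf` with `undefined = TRUE` when no synonymous SNP was seen) and
#'   `snps_per_kb`.
#' @export
snpDnds <- function(orfset, variants, ids = orfIds(orfset), min_daf = 0.01) {
  v <- variants
  keep <- v$snp_strand != "-" & !v$in_repeat & (is.na(v$daf) | v$daf >= min_daf)
  v <- v[keep]
  vkey <- paste(as.character(GenomicRanges::seqnames(v)),
                GenomicRanges::start(v))
  vmap <- split(seq_along(vkey), vkey)     # all variants per genomic position
  vref <- v$ref; valt <- v$alt
  nS <- nN <- 0L
  sSites <- nSites <- 0
  totNt <- 0
  allIdx <- match(ids, orfIds(orfset))
  ranges <- as.list(orfset@ranges[ids])
  for (j in seq_along(ids)) {
    i <- allIdx[j]
    rec <- orfset@info[i, ]
    chain <- ranges[[j]]
    strand <- exonStrand(chain)
    pos <- txPositions(chain, strand)        # ORF 5'->3' genomic positions
    codons <- splitCodons(rec$nt_seq)
    nc <- length(codons)
    inner <- seq(2L, nc - 1L)                # start & stop codons excluded
    st <- codonSites(codons[inner])
    sSites <- sSites + sum(st$s_sites)
    nSites <- nSites + sum(st$n_sites)
    totNt <- totNt + 3L * length(inner)
    chrom <- as.character(GenomicRanges::seqnames(chain)[1L])
    posKey <- paste(chrom, pos)
    qis <- which(posKey %in% names(vmap))
    for (qi in qis) {
      cidx <- (qi - 1L) %/% 3L + 1L
      if (cidx == 1L || cidx == nc) next
      off <- (qi - 1L) %% 3L + 1L
      cod <- codons[cidx]
      for (k in vmap[[posKey[qi]]]) {
        ref <- vref[k]; alt <- valt[k]
        if (strand == "-") { ref <- revComp(ref); alt <- revComp(alt) }
        if (substr(cod, off, off) != ref) next # annotation/genome mismatch
        mut <- cod
        substr(mut, off, off) <- alt
        aaRef <- codon2aa()[[cod]]
        aaMut <- codon2aa()[[mut]]
        if (aaMut == aaRef && aaMut != "*") nS <- nS + 1L else nN <- nN + 1L
      }
    }
  }
  undefined <- nS == 0L
  dnds <- if (undefined) Inf else (nN / nSites) / (nS / sSites)
  list(n_syn = nS, n_nonsyn = nN, s_sites = sSites, n_sites = nSites,
       dnds = dnds, undefined = undefined,
       snps_per_kb = 1000 * (nS + nN) / max(totNt, 1L))
}

#' Reciprocal chi-squared tests for dN/dS depletion
#'
#' For each of two SNP-count aggregates (candidates and controls), tests
#' the observed (non-synonymous, synonymous) SNP counts against the
#' expectation proportional to the (non-synonymous, synonymous) site
#' counts with a one-sided chi-squared test (alternative: non-synonymous
#' SNPs depleted, i.e. dN/dS < 1). The reported P value is the larger of
#' the two.
#'
#' @param cand,ctrl lists from [snpDnds()].
#' @return list with `p_cand`, `p_ctrl` and `p` (their max).
#' @export
reciprocalDndsTest <- function(cand, ctrl) {
  one <- function(x) {
    tot <- x$n_nonsyn + x$n_syn
    if (tot == 0L) return(1)
    pExp <- x$n_sites / (x$n_sites + x$s_sites)
    ts <- suppressWarnings(
      stats::chisq.test(c(x$n_nonsyn, x$n_syn), p = c(pExp, 1 - pExp)))
    p2 <- ts$p.value
    depleted <- x$n_nonsyn / tot < pExp
    if (depleted) p2 / 2 else 1 - p2 / 2
  }
  pc <- one(cand); pk <- one(ctrl)
  list(p_cand = pc, p_ctrl = pk, p = max(pc, pk))
}
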