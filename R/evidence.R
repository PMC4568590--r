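#' Metagene 5' offsets and phasing from ribosome-profiling reads
#'
#' Aggregates read 5' ends in windows around annotated CDS starts (in
#' spliced transcript coordinates) and determines, per read length, the
#' 5'-end offset: among candidate offsets the one maximising the fraction
#' of reads in frame with the start codon, ties broken by the sharpest
#' initiation peak (read count at relative position `-offset`), then by
#' the smallest offset. Read lengths with fewer than `min_reads` reads in
#' the windows are excluded with a message.
#'
#' @param reads data.frame of 5' ends: `chrom`, `pos` (1-based genomic
#'   position of the 5' base), `strand`, `length` (read length).
#' @param txset a [TranscriptSet] with annotated CDS.
#' @param window half-window (nt) around the CDS start.
#' @param max_offset largest candidate offset.
#' @param min_reads minimum reads per length.
#' @return data.frame per read length: `length`, `offset`,
#'   `phasing_fraction`, `n_reads`.
#' @export
metageneOffsets <- function(reads, txset, window = 50L, max_offset = 30L,
                            min_reads = 100L) {
  rel <- integer(0); rlen <- integer(0)
  info <- txInfo(txset)
  for (id in info$tx_id[vapply(txset@cds[info$tx_id], length, integer(1)) > 0L]) {
    ex <- txset@exons[[id]]
    strand <- exonStrand(ex)
    cd <- txset@cds[[id]]
    cdsStartTx <- min(genomeToTranscript(txset, id,
      c(GenomicRanges::start(cd), GenomicRanges::end(cd))), na.rm = TRUE)
    chrom <- as.character(GenomicRanges::seqnames(ex)[1L])
    r <- reads[reads$chrom == chrom & reads$strand == strand, , drop = FALSE]
    if (nrow(r) == 0L) next
    txpos <- genomeToTranscript(txset, id, r$pos)
    ok <- !is.na(txpos)
    d <- txpos[ok] - cdsStartTx
    inWin <- d >= -window & d < window
    rel <- c(rel, d[inWin])
    rlen <- c(rlen, r$length[ok][inWin])
  }
  out <- list()
  for (L in sort(unique(rlen))) {
    d <- rel[rlen == L]
    if (length(d) < min_reads) {
      message("read length ", L, " excluded (", length(d), " reads)")
      next
    }
    cand <- 0:max_offset
    frameFrac <- vapply(cand, function(o) mean((d + o) %% 3L == 0L), numeric(1))
    peak <- vapply(cand, function(o) sum(d == -o), numeric(1))
    best <- order(-frameFrac, -peak, cand)[1L]
    out[[length(out) + 1L]] <- data.frame(
      length = L, offset = cand[best], phasing_fraction = frameFrac[best],
      n_reads = length(d))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(length = integer(0), offset = integer(0),
               phasing_fraction = numeric(0), n_reads = integer(0))
}

#' Per-frame 5'-end counts over an ORF
#'
#' Counts offset-corrected read 5' ends per codon position over the ORF,
#' excluding the first and last codon. Frame 1 is the frame of the start
#' codon.
#'
#' @param orfset an [ORFSet]; `orf_id` one of its ids.
#' @param reads data.frame of (offset-corrected) 5' ends: `chrom`, `pos`,
#'   `strand`.
#' @param orf_id ORF id.
#' @return integer vector `c(F1, F2, F3)`.
#' @export
frameCounts <- function(orfset, orf_id, reads) {
  i <- match(orf_id, orfIds(orfset))
  chain <- orfset@ranges[[i]]
  strand <- exonStrand(chain)
  pos <- txPositions(chain, strand)
  chrom <- as.character(GenomicRanges::seqnames(chain)[1L])
  r <- reads[reads$chrom == chrom & reads$strand == strand, , drop = FALSE]
  idx <- match(r$pos, pos)                # 1-based position within the ORF
  idx <- idx[!is.na(idx)]
  n <- length(pos)
  idx <- idx[idx > 3L & idx <= n - 3L]    # exclude start and stop codons
  f <- (idx - 1L) %% 3L + 1L
  c(F1 = sum(f == 1L), F2 = sum(f == 2L), F3 = sum(f == 3L))
}

#' ORFscore: signed periodicity statistic
#'
#' With frame counts `F1, F2, F3` (frame 1 in frame with the start codon)
#' and their mean `Fbar`, the score is
#' `log2(sum_i (F_i - Fbar)^2 / Fbar + 1)`, negated when `F2 > F1` or
#' `F3 > F1`; all-zero counts give 0.
#'
#' @param counts numeric vector `c(F1, F2, F3)`.
#' @return numeric score.
#' @examples
#' orfScore(c(30, 0, 0))   # log2(61)
#' orfScore(c(10, 10, 10)) # 0
#' @export
orfScore <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  if (all(counts == 0)) return(0)
  fbar <- mean(counts)
  s <- log2(sum((counts - fbar)^2) / fbar + 1)
  if (counts[2L] > counts[1L] || counts[3L] > counts[1L]) -s else s
}

#' Dataset quality gate for translation calling
#'
#' Two-sample Kolmogorov-Smirnov D statistic between the ORFscores of
#' annotated (positive-control) and negative-control ORFs; the dataset
#' passes when D >= `min_d`.
#'
#' @param pos_scores,neg_scores numeric ORFscore vectors.
#' @param min_d separation threshold.
#' @return list with `D` and `pass`.
#' @export
datasetQuality <- function(pos_scores, neg_scores, min_d = 0.55) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("empty score group")
  D <- unname(suppressWarnings(
    stats::ks.test(pos_scores, neg_scores)$statistic))
  list(D = D, pass = D >= min_d)
}

#' Call translated ORFs from ORFscores
#'
#' @param scores numeric ORFscores.
#' @param cutoff translation call threshold (score >= cutoff).
#' @return logical vector.
#' @export
callTranslated <- function(scores, cutoff = 6) {
  scores >= cutoff
}

#' Expression level and specificity from an FPKM matrix
#'
#' Transcripts with all FPKM below `min_fpkm` are dropped; columns are
#' converted to TPM (`1e6 * FPKM / colSums(FPKM)`, so each sample sums to
#' one million); the mean expression is the average of non-zero TPM
#' values; specificity is the information content
#' `IC = (1 / log2 N) * sum_t r_t * log2(r_t * N)` over the normalised
#' log-expression distribution `r_t = log2(TPM_t + 1) / sum_s log2(TPM_s + 1)`
#' (0 for a uniform profile, 1 for single-sample expression; terms with
#' `r_t = 0` contribute 0).
#'
#' @param fpkm numeric matrix (transcripts x samples) with rownames.
#' @param min_fpkm expression floor.
#' @return list with `tpm` (matrix), `mean_tpm` and `ic` (named vectors).
#' @export
expressionMetrics <- function(fpkm, min_fpkm = 1e-4) {
  fpkm <- as.matrix(fpkm)
  if (ncol(fpkm) < 2L) stop("specificity needs at least 2 samples")
  keep <- apply(fpkm, 1L, function(x) any(x >= min_fpkm))
  fpkm <- fpkm[keep, , drop = FALSE]
  tpm <- sweep(fpkm, 2L, colSums(fpkm), "/") * 1e6
  meanTpm <- apply(tpm, 1L, function(x) if (any(x > 0)) mean(x[x > 0]) else 0)
  N <- ncol(tpm)
  ic <- apply(tpm, 1L, function(x) {
    l <- log2(x + 1)
    if (sum(l) == 0) return(0)
    r <- l / sum(l)
    nz <- r > 0
    sum(r[nz] * log2(r[nz] * N)) / log2(N)
  })
  list(tpm = tpm, mean_tpm = meanTpm, ic = ic)
}
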