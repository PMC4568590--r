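#' Transcript/genome coordinate mapping
#'
#' Coordinates are 1-based and inclusive on both sides. Transcript position
#' 1 is the 5'-most exonic base in transcript orientation (i.e. the highest
#' genomic coordinate for minus-strand models). `transcriptToGenome()` maps
#' a transcript interval to its spliced genomic interval chain (sorted by
#' genomic position); `genomeToTranscript()` maps exonic genomic positions
#' back. The two maps are mutually inverse on exonic positions.
#'
#' @param txset a [TranscriptSet].
#' @param tx_id a transcript id present in `txset`.
#' @param start,end 1-based transcript interval.
#' @param gpos vector of genomic positions.
#' @return `transcriptToGenome()`: a `GRanges` chain; `genomeToTranscript()`:
#'   an integer vector of transcript positions (`NA` for intronic/outside).
#' @export
transcriptToGenome <- function(txset, tx_id, start, end) {
  ex <- txset@exons[[tx_id]]
  if (is.null(ex)) stop("unknown transcript: ", tx_id)
  txChain(ex, exonStrand(ex), start, end)
}

#' @rdname transcriptToGenome
#' @export
genomeToTranscript <- function(txset, tx_id, gpos) {
  ex <- txset@exons[[tx_id]]
  if (is.null(ex)) stop("unknown transcript: ", tx_id)
  pos <- txPositions(ex, exonStrand(ex))
  match(gpos, pos)
}

exonStrand <- function(ex) {
  s <- as.character(GenomicRanges::strand(ex)[1L])
  if (s == "*") "+" else s
}

## genomic positions of a transcript in 5'->3' transcript order
txPositions <- function(ex, strand = exonStrand(ex)) {
  pos <- unlist(lapply(seq_along(ex), function(i)
    seq(GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i])),
    use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

## transcript interval [start, end] -> ascending genomic GRanges chain
txChain <- function(ex, strand, start, end) {
  w <- GenomicRanges::width(ex)
  L <- sum(w)
  if (start < 1L || end > L || start > end)
    stop(sprintf("transcript interval [%d,%d] outside 1..%d", start, end, L))
  if (strand == "-") {
    ## transcript runs from the last exon end downward
    tmp <- start
    start <- L - end + 1L
    end <- L - tmp + 1L
  }
  cw <- cumsum(w)
  off <- c(0L, cw[-length(cw)])
  chrom <- as.character(GenomicRanges::seqnames(ex)[1L])
  pieces <- list()
  for (i in seq_along(ex)) {
    lo <- max(start, off[i] + 1L)
    hi <- min(end, cw[i])
    if (lo > hi) next
    gs <- GenomicRanges::start(ex)[i] + (lo - off[i] - 1L)
    ge <- GenomicRanges::start(ex)[i] + (hi - off[i] - 1L)
    pieces[[length(pieces) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, pieces)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1L], m[, 2L]),
                         strand = strand)
}

## genomic positions of transcript extended into flanking genomic sequence:
## n_up bases 5' of transcript position 1, n_down bases 3' of the last
txPositionsExtended <- function(ex, strand, n_up, n_down) {
  pos <- txPositions(ex, strand)
  if (strand == "-") {
    up <- if (n_up > 0L) seq(pos[1L] + n_up, pos[1L] + 1L) else integer(0)
    dn <- if (n_down > 0L) seq(pos[length(pos)] - 1L,
                               pos[length(pos)] - n_down) else integer(0)
  } else {
    up <- if (n_up > 0L) seq(pos[1L] - n_up, pos[1L] - 1L) else integer(0)
    dn <- if (n_down > 0L) seq(pos[length(pos)] + 1L,
                               pos[length(pos)] + n_down) else integer(0)
  }
  c(up, pos, dn)
}
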