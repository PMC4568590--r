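#' Conservation step at the stop codon of an annotated CDS
#'
#' Mean conservation over the `width` spliced-transcript bases immediately
#' 5' of the stop codon minus the mean over the `width` bases immediately
#' 3' of it (the stop codon itself is in neither window). Windows truncated
#' by the transcript end use the available bases and set `clipped`.
#'
#' @param txset a [TranscriptSet]; `tx_id` a coding transcript in it.
#' @param tx_id transcript id.
#' @param track a [ConservationTrack].
#' @param width window size (nt) on each side.
#' @param stop_in_cds does the annotated CDS chain include the stop codon?
#' @return list with `step`, `inside`, `outside`, `clipped`.
#' @export
stopStep <- function(txset, tx_id, track, width = 25L, stop_in_cds = FALSE) {
  ex <- txset@exons[[tx_id]]
  cd <- txset@cds[[tx_id]]
  if (length(cd) == 0L) stop("transcript has no annotated CDS: ", tx_id)
  strand <- exonStrand(ex)
  chrom <- as.character(GenomicRanges::seqnames(ex)[1L])
  pos <- txPositions(ex, strand)
  cdsTx <- range(genomeToTranscript(txset, tx_id,
    c(GenomicRanges::start(cd), GenomicRanges::end(cd))), na.rm = TRUE)
  stopEnd <- if (stop_in_cds) cdsTx[2L] else cdsTx[2L] + 3L
  insideIdx <- seq(stopEnd - 2L - width, stopEnd - 3L)    # 5' of stop codon
  outsideIdx <- seq(stopEnd + 1L, stopEnd + width)
  clip <- function(i) i[i >= 1L & i <= length(pos)]
  ii <- clip(insideIdx); oi <- clip(outsideIdx)
  if (length(ii) == 0L || length(oi) == 0L)
    stop("no bases available around the stop codon of ", tx_id)
  clipped <- length(ii) < width || length(oi) < width
  inside <- mean(trackValues(track, chrom, pos[ii]))
  outside <- mean(trackValues(track, chrom, pos[oi]))
  list(step = inside - outside, inside = inside, outside = outside,
       clipped = clipped)
}

#' Diagnostics for a 3'UTR sORF (dORF) against its host CDS
#'
#' All quantities are computed in spliced transcript coordinates of the
#' host transcript: the conservation step at the host CDS stop
#' ([stopStep()]), the distance from the annotated stop codon to the dORF
#' start, the reading frame of the dORF start relative to the CDS frame
#' (0 = same frame), the number of stop codons in the CDS frame between
#' the annotated stop and the dORF start, and whether the dORF shares
#' >= 1 bp with annotated CDS exons of any isoform.
#'
#' @param orfset an [ORFSet]; `orf_id` a `utr3`-category ORF in it.
#' @param orf_id ORF id.
#' @param txset the host [TranscriptSet].
#' @param tx_seqs named `DNAStringSet` from [transcriptSeqs()].
#' @param track a [ConservationTrack].
#' @param cds_ref CDS reference for the overlap flag.
#' @param stop_in_cds see [stopStep()].
#' @return one-row data.frame: `orf_id`, `host_tx`, `stop_step`,
#'   `distance_to_cds_stop`, `frame_offset`, `n_intervening_stops`,
#'   `overlaps_annotated_cds`.
#' @export
dorfStats <- function(orfset, orf_id, txset, tx_seqs, track,
                      cds_ref = cdsReference(txset), stop_in_cds = FALSE) {
  i <- match(orf_id, orfIds(orfset))
  if (is.na(i)) stop("unknown ORF id: ", orf_id)
  rec <- orfset@info[i, ]
  host <- NULL
  for (id in rec$tx_ids[[1L]]) {
    if (length(txset@cds[[id]]) > 0L) { host <- id; break }
  }
  if (is.null(host)) stop("no coding host transcript for ", orf_id)
  cd <- txset@cds[[host]]
  cdsTx <- range(genomeToTranscript(txset, host,
    c(GenomicRanges::start(cd), GenomicRanges::end(cd))), na.rm = TRUE)
  stopEnd <- if (stop_in_cds) cdsTx[2L] else cdsTx[2L] + 3L
  ## dORF start position on the host transcript
  chain <- orfset@ranges[[i]]
  strand <- exonStrand(txset@exons[[host]])
  g5 <- if (strand == "-") max(GenomicRanges::end(chain)) else
    min(GenomicRanges::start(chain))
  dorfStart <- genomeToTranscript(txset, host, g5)
  if (is.na(dorfStart) || dorfStart <= stopEnd)
    stop(orf_id, " does not start downstream of the host CDS stop")
  distance <- dorfStart - stopEnd - 1L
  frameOffset <- (dorfStart - cdsTx[1L]) %% 3L
  ## stop codons in the CDS frame between the annotated stop and dORF start
  seq <- as.character(tx_seqs[[host]])
  interPos <- seq(stopEnd + 1L, dorfStart - 1L, by = 3L)
  interPos <- interPos[interPos + 2L < dorfStart]
  nStops <- if (length(interPos) == 0L) 0L else
    sum(substring(seq, interPos, interPos + 2L) %in% STOP_CODONS)
  ss <- stopStep(txset, host, track, stop_in_cds = stop_in_cds)
  data.frame(orf_id = orf_id, host_tx = host, stop_step = ss$step,
             distance_to_cds_stop = distance, frame_offset = frameOffset,
             n_intervening_stops = nStops,
             overlaps_annotated_cds = overlapsRef(chain, cds_ref),
             stringsAsFactors = FALSE)
}

#' Match candidate stop codons to a published readthrough list
#'
#' Exact genomic stop-codon coordinate matching (chromosome, strand, and
#' the genomic interval of the stop codon).
#'
#' @param candidate_stops,published_stops data.frames with columns `id`,
#'   `chrom`, `start`, `end`, `strand` (1-based stop-codon interval).
#' @return character vector of candidate ids with a published match.
#' @export
matchReadthrough <- function(candidate_stops, published_stops) {
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  candidate_stops$id[key(candidate_stops) %in% key(published_stops)]
}

#' Genomic stop-codon intervals of ORFs
#'
#' @param orfset an [ORFSet].
#' @return data.frame `id`, `chrom`, `start`, `end`, `strand` of each
#'   ORF's stop codon (last 3 nt in transcript orientation).
#' @export
orfStopCoords <- function(orfset) {
  ids <- orfIds(orfset)
  rows <- lapply(ids, function(id) {
    chain <- orfset@ranges[[match(id, ids)]]
    strand <- exonStrand(chain)
    pos <- txPositions(chain, strand)
    stopPos <- sort(utils::tail(pos, 3L))
    data.frame(id = id,
               chrom = as.character(GenomicRanges::seqnames(chain)[1L]),
               start = stopPos[1L], end = stopPos[3L], strand = strand,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
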