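#' Conserved coding exons
#'
#' Retains exons whose reading-frame conservation (number of aligned
#' species without frameshifting indels) reaches `threshold`. The
#' threshold is typically chosen with [rocMinAvgErrorCutoff()] on the
#' frame-conservation counts of positive vs. negative training ORFs.
#'
#' @param exons `GRanges` of annotated coding exons.
#' @param counts integer vector of per-exon frame-conservation counts
#'   (parallel to `exons`).
#' @param threshold minimum count.
#' @return `GRanges` of retained exons with a `frame_species` column.
#' @export
buildConservedExons <- function(exons, counts, threshold) {
  stopifnot(length(exons) == length(counts))
  keep <- counts >= threshold
  out <- exons[keep]
  S4Vectors::mcols(out)$frame_species <- counts[keep]
  out
}

#' Two-pass overlap filter on predicted sORFs
#'
#' Removes predictions whose conservation signal cannot be unambiguously
#' assigned. Pass 1 keeps annotated sORFs, and other sORFs only when they
#' do not intersect (>= 1 bp) a conserved coding exon. Pass 2 drops any
#' remaining prediction strictly contained (same strand, genomic interval
#' chain containment) in a longer predicted ORF that itself passed pass 1;
#' the retained representative of a containment family is the longest ORF,
#' ties broken by the best selection score.
#'
#' @param orfset an [ORFSet] (the full analyzed set).
#' @param predicted_ids ids of SVM-predicted ORFs (candidates to filter).
#' @param conserved_exons `GRanges` from [buildConservedExons()].
#' @param scores named numeric selection scores for at least the predicted
#'   ORFs.
#' @param strand_aware should pass-1 intersection require matching strand?
#'   (default FALSE: any-strand 1 bp overlap rejects).
#' @return data.frame with `orf_id`, `kept`, `reason` (`NA`,
#'   `conserved_exon_overlap` or `contained_in_longer`).
#' @export
applyOverlapFilter <- function(orfset, predicted_ids, conserved_exons, scores,
                               strand_aware = FALSE) {
  info <- orfset@info
  ids <- predicted_ids
  stopifnot(all(ids %in% info$orf_id))
  cats <- stats::setNames(info$category, info$orf_id)[ids]
  annotated <- !is.na(cats) & cats == "annotated"

  ## pass 1: conserved-coding-exon intersection (one batched overlap query)
  flat <- unlist(orfset@ranges[ids], use.names = FALSE)
  owner <- rep(ids, lengths(orfset@ranges[ids]))
  hit <- suppressWarnings(
    IRanges::findOverlaps(flat, conserved_exons, minoverlap = 1L,
                          ignore.strand = !strand_aware))
  hitsExon <- ids %in% owner[unique(S4Vectors::queryHits(hit))]
  names(hitsExon) <- ids
  pass1 <- annotated | !hitsExon
  reason <- rep(NA_character_, length(ids))
  reason[!pass1] <- "conserved_exon_overlap"

  ## pass 2: containment in a longer prediction that passed pass 1
  survivors <- ids[pass1]
  containers <- ids[pass1 & !hitsExon]   # a container must be exon-clean itself
  len <- stats::setNames(info$n_codons, info$orf_id)
  sc <- scores[survivors]
  kept <- pass1
  names(kept) <- ids
  if (length(survivors) > 1L && length(containers)) {
    chains <- as.list(orfset@ranges[survivors])
    ## bounding boxes for a cheap prefilter before chain-level containment
    bb <- t(vapply(survivors, function(id) {
      ch <- chains[[id]]
      c(min(GenomicRanges::start(ch)), max(GenomicRanges::end(ch)))
    }, numeric(2)))
    chromOf <- vapply(survivors, function(id)
      as.character(GenomicRanges::seqnames(chains[[id]])[1L]), character(1))
    strandOf <- vapply(survivors, function(id)
      as.character(GenomicRanges::strand(chains[[id]])[1L]), character(1))
    for (a in survivors) {
      ia <- match(a, survivors)
      for (b in containers) {
        if (a == b) next
        ib <- match(b, survivors)
        if (chromOf[ib] != chromOf[ia] || strandOf[ib] != strandOf[ia]) next
        if (bb[ib, 1L] > bb[ia, 1L] || bb[ib, 2L] < bb[ia, 2L]) next
        if (len[b] < len[a]) next
        if (len[b] == len[a] &&
            !(sc[b] > sc[a] || (sc[b] == sc[a] && b < a))) next
        if (chainContained(chains[[a]], chains[[b]])) {
          kept[a] <- FALSE
          reason[match(a, ids)] <- "contained_in_longer"
          break
        }
      }
    }
  }
  data.frame(orf_id = ids, kept = unname(kept), reason = reason,
             stringsAsFactors = FALSE)
}

## strict same-strand genomic containment of chain a inside chain b
chainContained <- function(a, b) {
  if (as.character(GenomicRanges::strand(a)[1L]) !=
      as.character(GenomicRanges::strand(b)[1L])) return(FALSE)
  if (identical(chainKey(a), chainKey(b))) return(FALSE)
  hits <- IRanges::findOverlaps(a, b, type = "within")
  length(unique(S4Vectors::queryHits(hits))) == length(a)
}
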