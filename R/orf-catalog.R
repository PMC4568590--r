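#' Build a catalog of candidate ORFs from a transcript annotation
#'
#' Scans every transcript's spliced sequence with [scanOrfs()] (both strands
#' for unstranded models), maps hits to spliced genomic coordinate chains,
#' and combines ORFs from different transcripts with identical genomic
#' coordinates and amino acid sequence into groups.
#'
#' @param txset a [TranscriptSet].
#' @param genome named `DNAStringSet` of chromosome sequences.
#' @param min_nt minimum ORF span in nucleotides (stop codon included).
#' @return an [ORFSet] with category `NA` (see [classifyOrfs()]).
#' @export
buildOrfCatalog <- function(txset, genome, min_nt = 27L) {
  seqs <- transcriptSeqs(txset, genome)
  info <- txInfo(txset)
  perTx <- list()
  for (i in seq_len(nrow(info))) {
    id <- info$tx_id[i]
    hits <- scanOrfs(seqs[[id]], both_strands = !info$stranded[i], min_nt = min_nt)
    if (nrow(hits) == 0L) next
    hits$tx_id <- id
    perTx[[length(perTx) + 1L]] <- hits
  }
  groupOrfs(perTx, txset)
}

#' Group per-transcript ORF hits by genomic coordinates and peptide
#'
#' One output record per (genomic interval chain, amino acid sequence)
#' pair; transcript ids of all members are concatenated.
#'
#' @param per_tx_hits list of data.frames from [scanOrfs()], each with a
#'   `tx_id` column.
#' @param txset the [TranscriptSet] the hits came from.
#' @return an [ORFSet].
#' @export
groupOrfs <- function(per_tx_hits, txset) {
  hits <- if (length(per_tx_hits)) do.call(rbind, per_tx_hits) else NULL
  if (is.null(hits) || nrow(hits) == 0L) return(emptyOrfSet())
  chains <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ex <- txset@exons[[hits$tx_id[i]]]
    strand <- exonStrand(ex)
    if (hits$scan_strand[i] == "-") strand <- flipStrand(strand)
    chains[[i]] <- txChain(ex, strand, hits$tx_start[i], hits$tx_end[i])
  }
  keys <- paste(vapply(chains, chainKey, character(1)), hits$aa_seq)
  grp <- match(keys, unique(keys))
  ord <- order(grp, hits$tx_id)
  hits <- hits[ord, , drop = FALSE]
  chains <- chains[ord]
  grp <- grp[ord]
  first <- !duplicated(grp)
  idx <- which(first)
  n <- length(idx)
  ids <- sprintf("orf%05d", seq_len(n))
  txids <- IRanges::CharacterList(split(hits$tx_id, grp))
  names(txids) <- ids
  rng <- GenomicRanges::GRangesList(chains[first])
  names(rng) <- ids
  info <- DataFrame(
    orf_id = ids,
    tx_ids = txids,
    rep_tx = hits$tx_id[first],
    tx_start = hits$tx_start[first],
    tx_end = hits$tx_end[first],
    scan_strand = hits$scan_strand[first],
    n_codons = hits$n_codons[first],
    nt_seq = hits$nt_seq[first],
    aa_seq = hits$aa_seq[first],
    category = rep(NA_character_, n),
    uses_most_upstream_aug = rep(TRUE, n))
  rownames(info) <- ids
  out <- new("ORFSet", ranges = rng, info = info)
  validObject(out)
  out
}

emptyOrfSet <- function() {
  new("ORFSet", ranges = GenomicRanges::GRangesList(),
      info = DataFrame(orf_id = character(0),
                       tx_ids = IRanges::CharacterList(),
                       rep_tx = character(0), tx_start = integer(0),
                       tx_end = integer(0), scan_strand = character(0),
                       n_codons = integer(0), nt_seq = character(0),
                       aa_seq = character(0), category = character(0),
                       uses_most_upstream_aug = logical(0)))
}

flipStrand <- function(s) c(`+` = "-", `-` = "+", `*` = "*")[[s]]

#' Union of annotated CDS intervals
#'
#' @param txset a [TranscriptSet].
#' @param extra optional additional `GRanges` of CDS intervals (e.g. from a
#'   second annotation source).
#' @return reduced `GRanges` used as the CDS reference for classification
#'   and overlap filtering (1 bp minimum overlap convention).
#' @export
cdsReference <- function(txset, extra = NULL) {
  cds <- unlist(txset@cds, use.names = FALSE)
  if (!is.null(extra)) cds <- c(cds, GenomicRanges::granges(extra))
  GenomicRanges::reduce(cds, ignore.strand = TRUE)
}

KNOWN_BIOTYPES <- c("protein_coding", "lincRNA", "miRNA", "rRNA", "tRNA",
                    "snRNA", "snoRNA", "pseudogene", "processed_pseudogene",
                    "unprocessed_pseudogene", "sense_overlapping",
                    "nonsense_mediated_decay", "retained_intron", "misc_RNA",
                    "antisense")

#' Classify ORF groups by genomic context
#'
#' Assigns each ORF group the first matching category in the fixed order
#' `annotated` (exact match to the CDS of a canonical protein-coding
#' transcript, stop codon included or not) -> `pseudogene` -> `ncRNA`
#' (miRNA/rRNA/tRNA/snRNA/snoRNA) -> `utr3` -> `utr5` (inside the
#' UTR of a canonical coding member transcript with zero CDS-reference
#' overlap) -> `cds_overlap` (partial overlap with the CDS reference) ->
#' `other` -> `lincRNA`. Finally, groups fully contained in annotated CDS
#' are re-assigned to `cds_overlap` unless the group is in `other`.
#'
#' @param orfset an [ORFSet].
#' @param txset the [TranscriptSet] the ORFs came from.
#' @param cds_ref CDS reference `GRanges` (default [cdsReference()] of
#'   `txset`).
#' @return the [ORFSet] with the `category` column filled in.
#' @export
classifyOrfs <- function(orfset, txset, cds_ref = cdsReference(txset)) {
  info <- orfset@info
  tinfo <- txInfo(txset)
  rownames(tinfo) <- tinfo$tx_id
  cats <- character(nrow(info))
  cdsKeys <- cdsChainKeys(txset)
  for (i in seq_len(nrow(info))) {
    chain <- orfset@ranges[[i]]
    members <- info$tx_ids[[i]]
    mt <- tinfo[members, , drop = FALSE]
    cats[i] <- classifyOne(chain, info[i, ], mt, txset, cds_ref, cdsKeys)
  }
  ## final re-assignment: fully CDS-contained groups (except 'other')
  contained <- containedInRef(orfset@ranges, cds_ref)
  move <- contained & !cats %in% c("annotated", "pseudogene", "other",
                                   "cds_overlap", "utr3", "utr5")
  cats[move] <- "cds_overlap"
  orfset@info$category <- cats
  orfset
}

## keys of annotated CDS chains, with and without a 3-nt stop extension
cdsChainKeys <- function(txset) {
  keys <- character(0)
  for (id in txIds(txset)) {
    cd <- txset@cds[[id]]
    if (length(cd) == 0L) next
    if (txInfo(txset)[match(id, txIds(txset)), "tx_biotype"] != "protein_coding")
      next
    cd <- GenomicRanges::sort(cd)
    keys <- c(keys, chainKey(cd), chainKey(extendChain3(cd)))
  }
  unique(keys)
}

## extend a sorted CDS chain by 3 nt at its 3' end (annotation convention
## where the stop codon is not part of the CDS)
extendChain3 <- function(cd) {
  s <- exonStrand(cd)
  n <- length(cd)
  if (s == "-") {
    GenomicRanges::start(cd)[1L] <- GenomicRanges::start(cd)[1L] - 3L
  } else {
    GenomicRanges::end(cd)[n] <- GenomicRanges::end(cd)[n] + 3L
  }
  cd
}

NC_BIOTYPES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA")

classifyOne <- function(chain, rec, mt, txset, cds_ref, cdsKeys) {
  bt <- unique(c(mt$tx_biotype, mt$gene_biotype))
  unknown <- setdiff(bt, KNOWN_BIOTYPES)
  if (length(unknown))
    warning("unknown biotype(s) ", paste(unknown, collapse = ", "),
            " treated as 'other'", call. = FALSE)
  if (chainKey(GenomicRanges::sort(chain)) %in% cdsKeys) return("annotated")
  if (any(grepl("pseudogene", bt))) return("pseudogene")
  if (any(bt %in% NC_BIOTYPES)) return("ncRNA")
  ov <- overlapsRef(chain, cds_ref)
  if (!ov) {
    pos <- utrPosition(chain, rec, mt, txset)
    if (pos == "utr3") return("utr3")
    if (pos == "utr5") return("utr5")
  }
  if (ov && !allContained(chain, cds_ref)) return("cds_overlap")
  if (any(mt$gene_biotype == "protein_coding") ||
      any(!bt %in% "lincRNA" & !bt %in% NC_BIOTYPES)) {
    if (all(bt == "lincRNA")) return("lincRNA")
    return("other")
  }
  "lincRNA"
}

overlapsRef <- function(chain, cds_ref) {
  length(suppressWarnings(
    IRanges::findOverlaps(chain, cds_ref, ignore.strand = TRUE,
                          minoverlap = 1L))) > 0L
}

allContained <- function(chain, cds_ref) {
  hits <- suppressWarnings(
    IRanges::findOverlaps(chain, cds_ref, type = "within",
                          ignore.strand = TRUE))
  length(unique(S4Vectors::queryHits(hits))) == length(chain)
}

containedInRef <- function(rangesList, cds_ref) {
  vapply(seq_along(rangesList),
         function(i) allContained(rangesList[[i]], cds_ref), logical(1))
}

## does the ORF lie entirely inside the 3'UTR (or 5'UTR) of a canonical
## coding member transcript?
utrPosition <- function(chain, rec, mt, txset) {
  coding <- mt$tx_id[mt$tx_biotype == "protein_coding"]
  for (id in coding) {
    cd <- txset@cds[[id]]
    if (length(cd) == 0L) next
    ex <- txset@exons[[id]]
    strand <- exonStrand(ex)
    cdsPos <- range(genomeToTranscript(txset, id,
                      c(GenomicRanges::start(cd), GenomicRanges::end(cd))),
                    na.rm = TRUE)
    orfPos <- genomeToTranscript(txset, id,
                c(GenomicRanges::start(chain), GenomicRanges::end(chain)))
    if (anyNA(orfPos)) next
    orfPos <- range(orfPos)
    if (orfPos[1L] > cdsPos[2L]) return("utr3")
    if (orfPos[2L] < cdsPos[1L]) return("utr5")
  }
  "none"
}
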