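#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame DFrame
#' @importClassesFrom GenomicRanges GRangesList
#' @importClassesFrom IRanges SimpleRleList
NULL

#' TranscriptSet: a merged transcript annotation
#'
#' Container for transcript models read from one or more annotation catalogs.
#' Exon and CDS structures are held as [GenomicRanges::GRangesList] objects
#' named by transcript id; per-transcript metadata (gene id, biotypes, source
#' catalog, strandedness) live in a `DataFrame`.
#'
#' @slot txinfo `DataFrame` with one row per transcript: `tx_id`, `gene_id`,
#'   `tx_biotype`, `gene_biotype`, `source_catalog`, `stranded`.
#' @slot exons `GRangesList` of exons per transcript, sorted by genomic
#'   position; exons of one transcript never overlap.
#' @slot cds `GRangesList` of CDS intervals per transcript (zero-length
#'   element where a transcript has no annotated CDS). CDS intervals are
#'   always contained in the exons.
#'
#' @seealso [readAnnotation()]
#' @export
setClass("TranscriptSet",
  representation(txinfo = "DataFrame", exons = "GRangesList", cds = "GRangesList")
)

setValidity("TranscriptSet", function(object) {
  msg <- NULL
  ids <- object@txinfo$tx_id
  nm <- function(x) if (is.null(names(x))) character(0) else names(x)
  if (!identical(nm(object@exons), ids))
    msg <- c(msg, "exons must be named by tx_id in txinfo order")
  if (!identical(nm(object@cds), ids))
    msg <- c(msg, "cds must be named by tx_id in txinfo order")
  ok <- vapply(seq_along(object@exons), function(i) {
    ex <- object@exons[[i]]
    if (length(ex) > 1L) {
      if (is.unsorted(GenomicRanges::start(ex))) return(FALSE)
      if (!IRanges::isDisjoint(ex)) return(FALSE)
    }
    cd <- object@cds[[i]]
    if (length(cd) > 0L) {
      hits <- IRanges::findOverlaps(cd, ex, type = "within")
      if (length(unique(S4Vectors::queryHits(hits))) < length(cd)) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, sprintf("invalid transcript model(s): %s",
                          paste(ids[!ok], collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' ORFSet: candidate open reading frames
#'
#' One record per ORF group (identical genomic coordinate chain and amino
#' acid sequence across isoforms). Spliced genomic structure is a
#' `GRangesList` named by ORF id; sequence, length, category and host
#' transcript bookkeeping live in a `DataFrame`.
#'
#' @slot ranges `GRangesList`, the spliced genomic interval chain per ORF,
#'   sorted by genomic position.
#' @slot info `DataFrame` with columns `orf_id`, `tx_ids` (CharacterList),
#'   `rep_tx`, `tx_start`, `tx_end` (1-based transcript coordinates on the
#'   representative transcript, stop codon included), `n_codons`, `nt_seq`,
#'   `aa_seq` (no stop symbol), `category`, `uses_most_upstream_aug`.
#'
#' @seealso [buildOrfCatalog()], [scanOrfs()]
#' @export
setClass("ORFSet",
  representation(ranges = "GRangesList", info = "DataFrame")
)

setValidity("ORFSet", function(object) {
  msg <- NULL
  info <- object@info
  rnm <- if (is.null(names(object@ranges))) character(0) else names(object@ranges)
  if (!identical(rnm, info$orf_id))
    msg <- c(msg, "ranges must be named by orf_id in info order")
  if (length(info$orf_id)) {
    if (!all(nchar(info$nt_seq) == 3L * info$n_codons))
      msg <- c(msg, "nt_seq length must equal 3 * n_codons")
    if (!all(info$n_codons >= 9L))
      msg <- c(msg, "ORFs must span at least 9 codons (27 nt)")
    if (!all(substr(info$nt_seq, 1L, 3L) == "ATG"))
      msg <- c(msg, "nt_seq must start with ATG")
    last <- substr(info$nt_seq, nchar(info$nt_seq) - 2L, nchar(info$nt_seq))
    if (!all(last %in% c("TAA", "TAG", "TGA")))
      msg <- c(msg, "nt_seq must end with a stop codon")
  }
  if (is.null(msg)) TRUE else msg
})

#' ConservationTrack: per-base conservation scores
#'
#' Sparse per-chromosome storage of a phastCons-like track as run-length
#' encoded vectors. Positions absent from the input file score the declared
#' default (0 unless set otherwise).
#'
#' @slot scores a `SimpleRleList`, one numeric `Rle` per chromosome.
#' @slot default numeric scalar returned for positions not covered.
#'
#' @seealso [readConservationTrack()], [trackValues()]
#' @export
setClass("ConservationTrack",
  representation(scores = "SimpleRleList", default = "numeric")
)

#' StitchedAlignment: per-species aligned rows over one ORF
#'
#' Rows are restricted to the ORF's reference positions (transcript
#' orientation); deletions relative to the reference appear as `-`,
#' insertions are tallied separately before stitching and enter only the
#' per-species flags.
#'
#' @slot refSpecies name of the reference species.
#' @slot refCodons character vector of reference codons (start through stop).
#' @slot rows named character vector, one gapped string of length
#'   `3 * length(refCodons)` per aligned species (reference excluded).
#' @slot flags `DataFrame` per species: `coverage`, `has_frameshift_indel`,
#'   `has_premature_stop`, `start_conserved`, `stop_conserved`,
#'   `splice_sites_conserved`.
#'
#' @seealso [stitchAndFlag()]
#' @export
setClass("StitchedAlignment",
  representation(refSpecies = "character", refCodons = "character",
                 rows = "character", flags = "DataFrame")
)

setValidity("StitchedAlignment", function(object) {
  msg <- NULL
  n <- 3L * length(object@refCodons)
  if (length(object@rows) && !all(nchar(object@rows) == n))
    msg <- c(msg, "all rows must have the reference length")
  if (!identical(rownames(object@flags), names(object@rows)))
    msg <- c(msg, "flags rownames must match row names")
  if (length(object@flags$coverage) &&
      (any(object@flags$coverage < 0) || any(object@flags$coverage > 1)))
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' SorfSVM: whitened linear support-vector classifier
#'
#' The four conservation features are whitened to zero mean and unit
#' variance on the training data; the decision is `sign(w . x + b)` with an
#' optional margin threshold.
#'
#' @slot center,scale named numeric vectors (training mean and sd per
#'   feature; sd of a constant feature is set to 1).
#' @slot weights named numeric weight vector in whitened feature space.
#' @slot bias numeric intercept.
#' @slot threshold decision threshold on the margin (default 0).
#'
#' @seealso [fitSvm()], [predictSvm()]
#' @export
setClass("SorfSVM",
  representation(center = "numeric", scale = "numeric", weights = "numeric",
                 bias = "numeric", threshold = "numeric")
)

setValidity("SorfSVM", function(object) {
  if (any(object@scale <= 0)) "feature scale must be > 0" else TRUE
})
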