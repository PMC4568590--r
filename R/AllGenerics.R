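#' @importFrom methods new show validObject is slot
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Accessors for TranscriptSet and ORFSet
#'
#' `txIds()`, `txInfo()`, `exonsBy()` and `cdsBy()` expose the transcript
#' table and structures of a [TranscriptSet]; `orfIds()`, `orfInfo()`,
#' `orfRanges()`, `orfCategories()`, `orfSeqs()` and `peptides()` do the same
#' for an [ORFSet].
#'
#' @param x a `TranscriptSet` or `ORFSet`.
#' @return vectors, `DataFrame`s, `GRangesList`s or `XStringSet`s as
#'   appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @rdname accessors
#' @export
setGeneric("txInfo", function(x) standardGeneric("txInfo"))
#' @rdname accessors
#' @export
setGeneric("exonsBy", function(x) standardGeneric("exonsBy"))
#' @rdname accessors
#' @export
setGeneric("cdsBy", function(x) standardGeneric("cdsBy"))
#' @rdname accessors
#' @export
setGeneric("orfIds", function(x) standardGeneric("orfIds"))
#' @rdname accessors
#' @export
setGeneric("orfInfo", function(x) standardGeneric("orfInfo"))
#' @rdname accessors
#' @export
setGeneric("orfRanges", function(x) standardGeneric("orfRanges"))
#' @rdname accessors
#' @export
setGeneric("orfCategories", function(x) standardGeneric("orfCategories"))
#' @rdname accessors
#' @export
setGeneric("orfSeqs", function(x) standardGeneric("orfSeqs"))
#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname accessors
setMethod("txIds", "TranscriptSet", function(x) x@txinfo$tx_id)
#' @rdname accessors
setMethod("txInfo", "TranscriptSet", function(x) x@txinfo)
#' @rdname accessors
setMethod("exonsBy", "TranscriptSet", function(x) x@exons)
#' @rdname accessors
setMethod("cdsBy", "TranscriptSet", function(x) x@cds)

#' @rdname accessors
setMethod("orfIds", "ORFSet", function(x) x@info$orf_id)
#' @rdname accessors
setMethod("orfInfo", "ORFSet", function(x) x@info)
#' @rdname accessors
setMethod("orfRanges", "ORFSet", function(x) x@ranges)
#' @rdname accessors
setMethod("orfCategories", "ORFSet", function(x) {
  stats::setNames(x@info$category, x@info$orf_id)
})
#' @rdname accessors
setMethod("orfSeqs", "ORFSet", function(x) {
  stats::setNames(Biostrings::DNAStringSet(x@info$nt_seq), x@info$orf_id)
})
#' @rdname accessors
setMethod("peptides", "ORFSet", function(x) {
  stats::setNames(Biostrings::AAStringSet(x@info$aa_seq), x@info$orf_id)
})

setMethod("show", "TranscriptSet", function(object) {
  bt <- table(object@txinfo$tx_biotype)
  cat(sprintf("TranscriptSet with %d transcripts (%d genes)\n",
              nrow(object@txinfo), length(unique(object@txinfo$gene_id))))
  cat("  biotypes:", paste(sprintf("%s(%d)", names(bt), bt), collapse = " "), "\n")
  if (any(!object@txinfo$stranded))
    cat(sprintf("  %d unstranded transcript(s)\n", sum(!object@txinfo$stranded)))
})

setMethod("show", "ORFSet", function(object) {
  cat(sprintf("ORFSet with %d ORF group(s)\n", nrow(object@info)))
  if (nrow(object@info)) {
    cat(sprintf("  codons: %d-%d\n", min(object@info$n_codons),
                max(object@info$n_codons)))
    if (!all(is.na(object@info$category))) {
      ct <- table(object@info$category)
      cat("  categories:", paste(sprintf("%s(%d)", names(ct), ct),
                                 collapse = " "), "\n")
    }
  }
})

setMethod("show", "StitchedAlignment", function(object) {
  cat(sprintf("StitchedAlignment: %d codons, %d aligned species\n",
              length(object@refCodons), length(object@rows)))
  if (length(object@rows))
    print(as.data.frame(object@flags))
})

setMethod("show", "SorfSVM", function(object) {
  cat("Linear SVM on whitened conservation features\n")
  w <- format(round(object@weights, 4))
  cat("  weights:", paste(names(object@weights), w, sep = "=", collapse = " "),
      "\n  bias:", round(object@bias, 4),
      " threshold:", object@threshold, "\n")
})

#' Subset an ORFSet
#'
#' @param x an [ORFSet]
#' @param i ORF ids, logical mask or integer indices
#' @param j,drop,... ignored
#' @export
setMethod("[", "ORFSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$orf_id)
  new("ORFSet", ranges = x@ranges[i], info = x@info[i, , drop = FALSE])
})

#' @describeIn accessors number of ORF groups
#' @export
setMethod("length", "ORFSet", function(x) nrow(x@info))
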