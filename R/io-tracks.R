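#' Read a per-base conservation track
#'
#' Reads a bedGraph or wig file of per-base scores in `[0, 1]` into a
#' [ConservationTrack]. Positions absent from the file read as `default`.
#'
#' @param path bedGraph/wig file.
#' @param default score for positions not covered by the file.
#' @return a [ConservationTrack].
#' @export
readConservationTrack <- function(path, default = 0) {
  gr <- rtracklayer::import(path)
  conservationTrack(gr, default = default)
}

#' @rdname readConservationTrack
#' @param gr a `GRanges` with a numeric `score` column.
#' @export
conservationTrack <- function(gr, default = 0) {
  scores <- if (length(gr) == 0L) methods::as(IRanges::RleList(), "SimpleRleList")
            else methods::as(GenomicRanges::coverage(gr, weight = "score"),
                             "SimpleRleList")
  new("ConservationTrack", scores = scores, default = default)
}

#' Per-base scores from a conservation track
#'
#' @param track a [ConservationTrack].
#' @param chrom chromosome name.
#' @param pos vector of 1-based genomic positions.
#' @return numeric vector of scores (`default` where the track is silent).
#' @export
trackValues <- function(track, chrom, pos) {
  out <- rep(track@default, length(pos))
  if (!chrom %in% names(track@scores)) return(out)
  r <- track@scores[[chrom]]
  ok <- pos >= 1L & pos <= length(r)
  if (any(ok)) out[ok] <- as.numeric(r[pos[ok]])
  out
}

#' Read single-nucleotide variants
#'
#' Reads a (possibly minimal) VCF into a `GRanges` of biallelic SNVs.
#' Multi-allelic records are split into biallelic ones. The INFO keys `DAF`
#' (derived allele frequency), `STRAND` (annotation strand of the SNP) and
#' `REPEAT` (flag: falls into a masked repeat) are picked up when present.
#' No filtering happens here; see [snpDnds()].
#'
#' @param path VCF file.
#' @return `GRanges` with metadata columns `ref`, `alt`, `daf`,
#'   `snp_strand`, `in_repeat`.
#' @export
readVariants <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  info <- VariantAnnotation::info(vcf)
  n <- length(rr)
  daf <- if ("DAF" %in% colnames(info)) as.numeric(info$DAF) else rep(NA_real_, n)
  strnd <- if ("STRAND" %in% colnames(info)) as.character(info$STRAND) else rep("+", n)
  inrep <- if ("REPEAT" %in% colnames(info)) {
    v <- info$REPEAT
    if (is.logical(v)) v else as.logical(as.integer(v))
  } else rep(FALSE, n)
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  gr <- GenomicRanges::granges(rr)[keep]
  S4Vectors::mcols(gr) <- DataFrame(ref = ref[keep], alt = alt[keep],
                                    daf = daf[keep], snp_strand = strnd[keep],
                                    in_repeat = inrep[keep])
  names(gr) <- NULL
  gr
}

#' Read a rooted species tree
#'
#' @param path Newick file.
#' @return an `ape` `phylo` object.
#' @export
readSpeciesTree <- function(path) {
  tree <- ape::read.tree(path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in species tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}
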