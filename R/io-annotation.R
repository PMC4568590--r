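#' Read and merge transcript annotation catalogs
#'
#' Reads a reference GTF/GFF annotation plus optional extra catalogs
#' (GTF or BED12, e.g. published lincRNA sets) into a single
#' [TranscriptSet]. Entries from non-reference catalogs receive the
#' biotype given by `extra_biotype` (lincRNA by default). Transcripts with
#' unknown strand (`*`) are kept and flagged unstranded so downstream ORF
#' scanning can handle both strands. Transcripts duplicating an already
#' seen exon chain are dropped (reference catalog wins).
#'
#' @param path reference annotation (GTF/GFF).
#' @param extra_catalogs character vector of additional GTF or BED12 files.
#' @param extra_biotype biotype assigned to extra-catalog transcripts.
#' @return a [TranscriptSet].
#' @export
readAnnotation <- function(path, extra_catalogs = NULL, extra_biotype = "lincRNA") {
  checkGtfLines(path)
  parts <- list(parseOneCatalog(path, source = "reference", biotype = NULL))
  for (cat in extra_catalogs) {
    src <- basename(cat)
    if (grepl("\\.bed[0-9]*$", cat, ignore.case = TRUE)) {
      parts <- c(parts, list(parseBed12Catalog(cat, src, extra_biotype)))
    } else {
      checkGtfLines(cat)
      parts <- c(parts, list(parseOneCatalog(cat, src, extra_biotype)))
    }
  }
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  exons <- do.call(c, lapply(parts, `[[`, "exons"))
  cds <- do.call(c, lapply(parts, `[[`, "cds"))
  if (is.null(info) || nrow(info) == 0L) {
    warning("annotation is empty: ", path)
    return(emptyTranscriptSet())
  }
  ## deduplicate identical exon chains (first catalog listed wins)
  keys <- vapply(seq_along(exons), function(i) chainKey(exons[[i]]), character(1))
  keep <- !duplicated(keys)
  info <- info[keep, , drop = FALSE]
  exons <- exons[keep]
  cds <- cds[keep]
  ts <- new("TranscriptSet", txinfo = info, exons = exons, cds = cds)
  validObject(ts)
  ts
}

emptyTranscriptSet <- function() {
  g <- GenomicRanges::GRangesList()
  new("TranscriptSet",
      txinfo = DataFrame(tx_id = character(0), gene_id = character(0),
                         tx_biotype = character(0), gene_biotype = character(0),
                         source_catalog = character(0), stranded = logical(0)),
      exons = g, cds = g)
}

## cheap structural pre-check so parse errors name the offending line
checkGtfLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 9L]
  if (length(bad))
    stop(sprintf("malformed GTF/GFF record in %s at line %d (%d field(s), expected 9)",
                 path, bad[1L], nf[which(body == bad[1L])]))
  invisible(TRUE)
}

parseOneCatalog <- function(path, source, biotype) {
  if (!any(!grepl("^(#|\\s*$)", readLines(path, warn = FALSE))))
    return(list(info = NULL, exons = GenomicRanges::GRangesList(),
                cds = GenomicRanges::GRangesList()))
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop(sprintf("cannot parse %s: %s",
                                                  path, conditionMessage(e))))
  if (length(gr) == 0L)
    return(list(info = NULL, exons = GenomicRanges::GRangesList(),
                cds = GenomicRanges::GRangesList()))
  m <- S4Vectors::mcols(gr)
  txid <- as.character(m$transcript_id)
  isEx <- m$type == "exon"
  isCds <- m$type == "CDS"
  ids <- unique(txid[isEx | isCds])
  ids <- ids[!is.na(ids)]
  g2 <- function(x, d) if (is.null(x)) rep(d, length(gr)) else as.character(x)
  geneid <- g2(m$gene_id, NA_character_)
  txbio <- g2(m$transcript_biotype, NA_character_)
  genebio <- g2(m$gene_biotype, NA_character_)
  exl <- cdl <- vector("list", length(ids))
  meta <- vector("list", length(ids))
  ord <- order(GenomicRanges::start(gr))
  gr <- gr[ord]; txid <- txid[ord]; isEx <- isEx[ord]; isCds <- isCds[ord]
  geneid <- geneid[ord]; txbio <- txbio[ord]; genebio <- genebio[ord]
  exIdx <- split(which(isEx), txid[isEx])
  cdsIdx <- split(which(isCds), txid[isCds])
  for (k in seq_along(ids)) {
    id <- ids[k]
    ei <- exIdx[[id]]
    ci <- cdsIdx[[id]]
    ex <- GenomicRanges::granges(gr[ei])
    cd <- if (is.null(ci)) GenomicRanges::GRanges() else GenomicRanges::granges(gr[ci])
    if (length(cd)) {
      within <- IRanges::findOverlaps(cd, ex, type = "within")
      if (length(unique(S4Vectors::queryHits(within))) < length(cd))
        stop(sprintf("transcript %s in %s: CDS outside exons", id, path))
    }
    exl[[k]] <- ex
    cdl[[k]] <- cd
    i1 <- if (length(ei)) ei[1L] else ci[1L]
    tb <- if (!is.null(biotype)) biotype else txbio[i1]
    gb <- if (!is.null(biotype)) biotype else genebio[i1]
    if (is.na(tb)) tb <- if (!is.na(gb)) gb else "unknown"
    if (is.na(gb)) gb <- tb
    meta[[k]] <- data.frame(
      tx_id = id,
      gene_id = if (is.na(geneid[i1])) id else geneid[i1],
      tx_biotype = tb, gene_biotype = gb,
      source_catalog = source,
      stranded = as.character(GenomicRanges::strand(gr[i1])) != "*",
      stringsAsFactors = FALSE)
  }
  info <- DataFrame(do.call(rbind, meta))
  exons <- GenomicRanges::GRangesList(exl)
  cds <- GenomicRanges::GRangesList(cdl)
  names(exons) <- names(cds) <- info$tx_id
  list(info = info, exons = exons, cds = cds)
}

parseBed12Catalog <- function(path, source, biotype) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L)
    return(list(info = NULL, exons = GenomicRanges::GRangesList(),
                cds = GenomicRanges::GRangesList()))
  ids <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("%s_%d", source, seq_along(gr))
  ids <- make.unique(ids)
  blocks <- if ("blocks" %in% names(S4Vectors::mcols(gr))) {
    bl <- rtracklayer::blocks(gr)
    names(bl) <- ids
    bl
  } else {
    b <- GenomicRanges::GRangesList(lapply(seq_along(gr),
           function(i) GenomicRanges::granges(gr[i])))
    names(b) <- ids
    b
  }
  info <- DataFrame(tx_id = ids, gene_id = ids,
                    tx_biotype = biotype, gene_biotype = biotype,
                    source_catalog = source,
                    stranded = as.character(GenomicRanges::strand(gr)) != "*")
  empty <- GenomicRanges::GRangesList(lapply(ids, function(i) GenomicRanges::GRanges()))
  names(empty) <- ids
  list(info = info, exons = blocks, cds = empty)
}

#' Spliced transcript sequences
#'
#' Extracts the spliced (exon-concatenated) sequence of each transcript in
#' transcript orientation (reverse-complemented for minus-strand models).
#' Unstranded transcripts are returned in plus-strand orientation.
#'
#' @param txset a [TranscriptSet].
#' @param genome a named [Biostrings::DNAStringSet] of chromosome sequences.
#' @return a named `DNAStringSet`, one sequence per transcript.
#' @export
transcriptSeqs <- function(txset, genome) {
  ids <- txIds(txset)
  out <- vapply(ids, function(id) {
    ex <- txset@exons[[id]]
    chrom <- as.character(GenomicRanges::seqnames(ex)[1L])
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    seqs <- substring(as.character(genome[[chrom]]),
                      GenomicRanges::start(ex), GenomicRanges::end(ex))
    s <- paste(seqs, collapse = "")
    if (as.character(GenomicRanges::strand(ex)[1L]) == "-") s <- revComp(s)
    s
  }, character(1))
  stats::setNames(Biostrings::DNAStringSet(out), ids)
}
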