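#' Read multiple-alignment blocks (MAF)
#'
#' Parses UCSC-style MAF blocks, normalising each block to reference
#' coordinates: columns where the reference row has a gap are removed and
#' recorded in a per-species insertion index (length of reference-absent
#' sequence after a given reference position), so every returned row has
#' exactly one character per reference base. Blocks are clipped to `region`
#' when given.
#'
#' @param path a MAF file, blocks sorted by reference coordinate.
#' @param region optional `GRanges` of length 1; blocks intersecting it are
#'   returned, clipped. An unknown chromosome gives an empty list with a
#'   warning.
#' @return a list of alignment blocks; each is a list with elements
#'   `chrom`, `start`, `end` (1-based inclusive), `ref` (reference species),
#'   `rows` (named character vector incl. the reference row, `-` marking
#'   deletions) and `ins` (named list of data.frames `pos`, `len`; an
#'   insertion of `len` bases follows reference position `pos`).
#' @export
readMaf <- function(path, region = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^a", lines)
  blocks <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    chunk <- lines[seq(bounds[b], bounds[b + 1L] - 1L)]
    srows <- grep("^s ", chunk, value = TRUE)
    if (length(srows) == 0L) next
    f <- lapply(strsplit(srows, "[ \t]+"), function(x) x[x != ""])
    species <- vapply(f, function(x) sub("\\..*$", "", x[2L]), character(1))
    chromsrc <- sub("^[^.]*\\.", "", f[[1L]][2L])
    refStart0 <- as.integer(f[[1L]][3L])
    texts <- toupper(vapply(f, function(x) x[7L], character(1)))
    names(texts) <- species
    blocks[[b]] <- normalizeBlock(chromsrc, refStart0, texts, species[1L])
  }
  blocks <- Filter(Negate(is.null), blocks)
  if (!is.null(region)) {
    chrom <- as.character(GenomicRanges::seqnames(region)[1L])
    rs <- GenomicRanges::start(region)[1L]
    re <- GenomicRanges::end(region)[1L]
    have <- vapply(blocks, `[[`, character(1), "chrom")
    if (!chrom %in% have) {
      warning("no alignment blocks on chromosome ", chrom)
      return(list())
    }
    blocks <- blocks[have == chrom]
    blocks <- lapply(blocks, clipBlock, rs, re)
    blocks <- Filter(Negate(is.null), blocks)
  }
  blocks
}

## drop reference-gap columns, building the insertion index
normalizeBlock <- function(chrom, refStart0, texts, refSpecies) {
  chars <- strsplit(texts, "", fixed = TRUE)
  refc <- chars[[1L]]
  isgap <- refc == "-"
  refpos <- cumsum(!isgap) + refStart0   # 1-based ref position per column
  ins <- list()
  if (any(isgap)) {
    r <- rle(isgap)
    colEnd <- cumsum(r$lengths)
    colStart <- colEnd - r$lengths + 1L
    gapRuns <- which(r$values)
    for (sp in names(texts)[-1L]) {
      spc <- chars[[sp]]
      recs <- NULL
      for (g in gapRuns) {
        cols <- seq(colStart[g], colEnd[g])
        len <- sum(spc[cols] != "-")
        if (len > 0L) {
          p <- if (colStart[g] == 1L) refStart0 else refpos[colStart[g] - 1L]
          recs <- rbind(recs, c(p, len))
        }
      }
      if (!is.null(recs))
        ins[[sp]] <- data.frame(pos = recs[, 1L], len = recs[, 2L])
    }
  }
  keep <- !isgap
  rows <- vapply(chars, function(x) paste(x[keep], collapse = ""), character(1))
  n <- sum(keep)
  list(chrom = chrom, start = refStart0 + 1L, end = refStart0 + n,
       ref = refSpecies, rows = rows, ins = ins)
}

clipBlock <- function(block, rs, re) {
  lo <- max(block$start, rs)
  hi <- min(block$end, re)
  if (lo > hi) return(NULL)
  i1 <- lo - block$start + 1L
  i2 <- hi - block$start + 1L
  rows <- substring(block$rows, i1, i2)
  names(rows) <- names(block$rows)
  ins <- lapply(block$ins, function(d) d[d$pos >= lo & d$pos <= hi, , drop = FALSE])
  ins <- Filter(function(d) nrow(d) > 0L, ins)
  list(chrom = block$chrom, start = lo, end = hi, ref = block$ref,
       rows = rows, ins = ins)
}

#' Write alignment blocks as MAF
#'
#' Inverse of [readMaf()]: re-inserts reference-gap columns from the
#' insertion index. Used by the synthetic-data generator.
#'
#' @param blocks list of blocks as returned by [readMaf()].
#' @param path output file.
#' @param insSeqs optional per-block named list of per-species inserted
#'   sequences (same shape as the insertion index); `N` bases are written
#'   when absent.
#' @export
writeMaf <- function(blocks, path, insSeqs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    species <- names(b$rows)
    chars <- strsplit(b$rows, "", fixed = TRUE)
    width <- b$end - b$start + 1L
    ## per reference position, per species inserted sequence (after that base)
    insAfter <- matrix("", nrow = length(species), ncol = width,
                       dimnames = list(species, NULL))
    for (sp in names(b$ins)) {
      d <- b$ins[[sp]]
      for (k in seq_len(nrow(d))) {
        j <- d$pos[k] - b$start + 1L
        if (j < 1L || j > width) next
        s <- NULL
        if (!is.null(insSeqs)) s <- insSeqs[[bi]][[sp]]$seq[k]
        if (is.null(s) || is.na(s)) s <- strrep("N", d$len[k])
        insAfter[sp, j] <- s
      }
    }
    extra <- apply(insAfter, 2L, function(x) max(nchar(x)))
    out <- lapply(species, function(sp) {
      v <- character(0)
      for (j in seq_len(width)) {
        v <- c(v, chars[[sp]][j])
        if (extra[j] > 0L) {
          s <- insAfter[sp, j]
          v <- c(v, strsplit(sprintf("%-*s", extra[j], s), "")[[1L]])
        }
      }
      paste(gsub(" ", "-", v, fixed = TRUE), collapse = "")
    })
    names(out) <- species
    writeLines(sprintf("a score=0"), con)
    for (sp in species) {
      txt <- out[[sp]]
      ungapped <- nchar(gsub("-", "", txt, fixed = TRUE))
      src <- if (sp == b$ref) paste0(sp, ".", b$chrom) else paste0(sp, ".chrU")
      writeLines(sprintf("s %s %d %d + %d %s", src,
                         if (sp == b$ref) b$start - 1L else 0L,
                         ungapped, 1000000L, txt), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
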