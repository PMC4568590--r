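#' Stitch alignment blocks over one ORF and flag species
#'
#' Restricts multiple-alignment blocks to the ORF's reference positions and
#' concatenates them in transcript orientation, computing per-species
#' coverage and flags. Indel flags are computed from the raw (un-stitched)
#' blocks: a species has a frameshifting indel iff any deletion run or any
#' recorded insertion within the ORF has a length that is not a multiple of
#' three. Splice-site conservation checks the donor/acceptor dinucleotides
#' of every intron of the ORF's interval chain.
#'
#' @param orfset an [ORFSet].
#' @param orf_id a single ORF id.
#' @param blocks alignment blocks from [readMaf()].
#' @return a [StitchedAlignment].
#' @export
stitchAndFlag <- function(orfset, orf_id, blocks) {
  i <- match(orf_id, orfIds(orfset))
  if (is.na(i)) stop("unknown ORF id: ", orf_id)
  chain <- orfset@ranges[[i]]
  strand <- exonStrand(chain)
  rec <- orfset@info[i, ]
  refPos <- txPositions(chain, "+")          # ascending genomic positions
  L <- length(refPos)
  chrom <- as.character(GenomicRanges::seqnames(chain)[1L])
  blocks <- Filter(function(b) b$chrom == chrom && b$start <= refPos[L] &&
                     b$end >= refPos[1L], blocks)
  refSpecies <- if (length(blocks)) blocks[[1L]]$ref else "reference"
  species <- unique(unlist(lapply(blocks, function(b) names(b$rows))))
  species <- setdiff(species, refSpecies)

  rows <- character(0)
  flags <- list()
  for (sp in species) {
    chars <- rep(".", L)                     # '.' = not covered by any block
    fsIndel <- FALSE
    for (b in blocks) {
      if (!sp %in% names(b$rows)) next
      lo <- max(b$start, refPos[1L]); hi <- min(b$end, refPos[L])
      idx <- which(refPos >= lo & refPos <= hi)
      if (length(idx) == 0L) next
      bc <- strsplit(b$rows[[sp]], "", fixed = TRUE)[[1L]]
      chars[idx] <- bc[refPos[idx] - b$start + 1L]
      if (sp %in% names(b$ins)) {
        d <- b$ins[[sp]]
        inORF <- d$pos >= refPos[1L] & d$pos < refPos[L]
        if (any(d$len[inORF] %% 3L != 0L)) fsIndel <- TRUE
      }
    }
    covered <- chars != "."
    coverage <- mean(chars %in% c("A", "C", "G", "T", "N"))
    ## deletion runs: '-' inside covered alignment
    del <- rle(chars == "-")
    if (any(del$values & del$lengths %% 3L != 0L)) fsIndel <- TRUE
    chars[!covered] <- "-"
    if (strand == "-") chars <- complementChars(rev(chars))
    row <- paste(chars, collapse = "")
    codons <- chunkCodons(chars)
    clean <- !grepl("[-N.]", codons)
    nc <- length(codons)
    premature <- any(codons[seq_len(nc - 1L)][clean[seq_len(nc - 1L)]] %in% STOP_CODONS)
    startCons <- clean[1L] && codons[1L] == "ATG"
    stopCons <- clean[nc] && codons[nc] %in% STOP_CODONS
    spliceCons <- spliceSitesConserved(chain, strand, blocks, sp)
    rows[sp] <- row
    flags[[sp]] <- data.frame(coverage = coverage,
                              has_frameshift_indel = fsIndel,
                              has_premature_stop = premature,
                              start_conserved = startCons,
                              stop_conserved = stopCons,
                              splice_sites_conserved = spliceCons)
  }
  fl <- if (length(flags)) DataFrame(do.call(rbind, flags)) else
    DataFrame(coverage = numeric(0), has_frameshift_indel = logical(0),
              has_premature_stop = logical(0), start_conserved = logical(0),
              stop_conserved = logical(0), splice_sites_conserved = logical(0))
  rownames(fl) <- names(rows)
  new("StitchedAlignment", refSpecies = refSpecies,
      refCodons = splitCodons(rec$nt_seq), rows = rows, flags = fl)
}

complementChars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-", `.` = ".")
  unname(comp[chars])
}

## species and reference characters at arbitrary genomic positions
blockCharsAt <- function(blocks, sp, pos) {
  out <- rep(NA_character_, length(pos))
  for (b in blocks) {
    if (!sp %in% names(b$rows)) next
    idx <- which(pos >= b$start & pos <= b$end)
    if (length(idx) == 0L) next
    bc <- strsplit(b$rows[[sp]], "", fixed = TRUE)[[1L]]
    out[idx] <- bc[pos[idx] - b$start + 1L]
  }
  out
}

## donor/acceptor dinucleotides of each intron identical to reference?
spliceSitesConserved <- function(chain, strand, blocks, sp) {
  n <- length(chain)
  if (n < 2L) return(TRUE)
  ref <- if (length(blocks)) blocks[[1L]]$ref else NULL
  pos <- integer(0)
  for (k in seq_len(n - 1L)) {
    e <- GenomicRanges::end(chain)[k]
    s <- GenomicRanges::start(chain)[k + 1L]
    pos <- c(pos, e + 1L, e + 2L, s - 2L, s - 1L)
  }
  spc <- blockCharsAt(blocks, sp, pos)
  refc <- if (is.null(ref)) rep(NA_character_, length(pos))
          else blockCharsAt(blocks, ref, pos)
  !anyNA(spc) && !anyNA(refc) && all(spc == refc) && !any(spc == "-")
}

#' Number of species with a conserved reading frame
#'
#' Counts non-reference species with at least 50 % sequence coverage of the
#' ORF and no frameshifting indels.
#'
#' @param stitched a [StitchedAlignment].
#' @param min_coverage coverage threshold (aligned non-gap reference
#'   positions / ORF length).
#' @return integer count.
#' @export
frameConservationCount <- function(stitched, min_coverage = 0.5) {
  fl <- stitched@flags
  sum(fl$coverage >= min_coverage & !fl$has_frameshift_indel)
}

#' Species conserving an ORF
#'
#' A species conserves an ORF when its start and stop codons and (for
#' spliced ORFs) splice sites are conserved and it has neither premature
#' stop codons nor frameshifting indels. The reference species is always
#' included.
#'
#' @param stitched a [StitchedAlignment].
#' @return character vector of species names.
#' @export
conservingSpecies <- function(stitched) {
  fl <- stitched@flags
  keep <- fl$start_conserved & fl$stop_conserved & fl$splice_sites_conserved &
    !fl$has_premature_stop & !fl$has_frameshift_indel
  c(stitched@refSpecies, rownames(fl)[keep])
}
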