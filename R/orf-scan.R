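#' Scan a spliced sequence for candidate ORFs
#'
#' Finds, for each in-frame stop codon, at most one ORF beginning at the
#' most upstream in-frame AUG with no intervening stop. ORFs must span at
#' least `min_nt` nucleotides (start codon through stop codon inclusive;
#' the default of 27 nt means >= 9 codons, 8 encoded amino acids). ORFs
#' containing an ambiguous base (`N`) in any codon are dropped, as are ORFs
#' truncated by the transcript end (no stop codon reached).
#'
#' @param seq spliced transcript sequence (character or `DNAString`),
#'   uppercase `ACGTN` alphabet.
#' @param both_strands also scan the reverse complement (used for
#'   unstranded transcript models).
#' @param min_nt minimum ORF span in nucleotides, stop codon included.
#' @return a data.frame with one row per ORF: `tx_start`, `tx_end` (1-based
#'   on the scanned sequence, stop codon included), `n_codons`, `nt_seq`,
#'   `aa_seq` (no stop symbol), `scan_strand` (`+`, or `-` for hits on the
#'   reverse complement, with coordinates on the reverse-complemented
#'   sequence).
#' @examples
#' scanOrfs(paste0("ATG", strrep("GCA", 8), "TAA"))
#' @export
scanOrfs <- function(seq, both_strands = FALSE, min_nt = 27L) {
  seq <- toupper(as.character(seq))
  if (!grepl("^[ACGTN]*$", seq))
    stop("sequence must use the ACGTN alphabet")
  out <- scanOneStrand(seq, "+", min_nt)
  if (both_strands)
    out <- rbind(out, scanOneStrand(revComp(seq), "-", min_nt))
  rownames(out) <- NULL
  out
}

scanOneStrand <- function(seq, strand, min_nt) {
  empty <- data.frame(tx_start = integer(0), tx_end = integer(0),
                      n_codons = integer(0), nt_seq = character(0),
                      aa_seq = character(0), scan_strand = character(0),
                      stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < min_nt) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  res <- list()
  for (frame in 0:2) {
    idx <- seq(frame + 1L, n - 2L, by = 3L)
    if (length(idx) < 2L) next
    codons <- paste0(chars[idx], chars[idx + 1L], chars[idx + 2L])
    isStop <- codons %in% STOP_CODONS
    isAtg <- codons == "ATG"
    ## most upstream AUG since the previous in-frame stop, per stop codon
    openAt <- NA_integer_
    for (i in seq_along(codons)) {
      if (isAtg[i] && is.na(openAt)) openAt <- i
      if (isStop[i]) {
        if (!is.na(openAt)) {
          span <- (i - openAt + 1L) * 3L
          nt <- substr(seq, idx[openAt], idx[i] + 2L)
          if (span >= min_nt && !grepl("N", nt, fixed = TRUE)) {
            aa <- paste(translateCodons(codons[openAt:(i - 1L)]), collapse = "")
            res[[length(res) + 1L]] <- data.frame(
              tx_start = idx[openAt], tx_end = idx[i] + 2L,
              n_codons = i - openAt + 1L, nt_seq = nt, aa_seq = aa,
              scan_strand = strand, stringsAsFactors = FALSE)
          }
          openAt <- NA_integer_
        }
      }
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out[order(out$tx_start, out$tx_end), , drop = FALSE]
}
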