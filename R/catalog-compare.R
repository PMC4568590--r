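#' Map an external sORF catalog onto the analyzed ORF set
#'
#' Matches entries of an external catalog to the analyzed ORFs and reports
#' one status per entry: `predicted_here` (matched an ORF in the
#' prediction set), `analyzed_only` (matched an analyzed ORF that was not
#' predicted) or `unmatched`. Coordinate entries match on an identical
#' genomic stop-codon interval; protein entries on exact amino-acid
#' equality; tryptic peptides on substring match with a preceding lysine
#' or arginine (or at the protein N-terminus, with or without the
#' initiator methionine cleaved).
#'
#' @param entries for `type = "coords"` a data.frame `id`, `chrom`,
#'   `start`, `end`, `strand` (stop-codon interval); otherwise a named
#'   character vector of sequences.
#' @param type `"coords"`, `"protein"` or `"peptide"`.
#' @param orfset the analyzed [ORFSet].
#' @param predicted_ids ids of the predicted subset.
#' @return data.frame `entry_id`, `status`, `matched_orfs`
#'   (semicolon-joined ids).
#' @export
matchCatalog <- function(entries, type = c("coords", "protein", "peptide"),
                         orfset, predicted_ids = character(0)) {
  type <- match.arg(type)
  ids <- orfIds(orfset)
  aa <- orfInfo(orfset)$aa_seq
  matched <- switch(type,
    coords = {
      stopifnot(is.data.frame(entries))
      stops <- orfStopCoords(orfset)
      key <- paste(stops$chrom, stops$start, stops$end, stops$strand)
      ekey <- paste(entries$chrom, entries$start, entries$end, entries$strand)
      lapply(ekey, function(k) ids[key == k])
    },
    protein = {
      stopifnot(is.character(entries))
      lapply(entries, function(s) ids[aa == s])
    },
    peptide = {
      stopifnot(is.character(entries))
      lapply(entries, function(p) ids[vapply(aa, trypticMatch, logical(1), p)])
    })
  entryIds <- if (is.data.frame(entries)) as.character(entries$id)
              else if (is.null(names(entries))) as.character(seq_along(entries))
              else names(entries)
  status <- vapply(matched, function(m) {
    if (length(m) == 0L) "unmatched"
    else if (any(m %in% predicted_ids)) "predicted_here"
    else "analyzed_only"
  }, character(1))
  data.frame(entry_id = entryIds, status = status,
             matched_orfs = vapply(matched, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

## tryptic-peptide match: substring preceded by K/R, or at the N-terminus
## (position 1, or position 2 after initiator-Met cleavage)
trypticMatch <- function(protein, peptide) {
  hits <- gregexpr(peptide, protein, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(FALSE)
  any(vapply(hits, function(p) {
    p <= 2L || substr(protein, p - 1L, p - 1L) %in% c("K", "R")
  }, logical(1)))
}
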