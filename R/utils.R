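## Small shared helpers: codon bookkeeping and sequence munging.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## codon -> amino acid, standard code; stops map to "*"
codon2aa <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

## split a DNA string into consecutive codons (length must be multiple of 3)
splitCodons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

## translate a vector of codons; codons with N or gaps give NA
translateCodons <- function(codons) {
  aa <- unname(codon2aa()[codons])
  aa
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## fast paste of a character matrix's columns into codon strings
chunkCodons <- function(chars) {
  n <- length(chars)
  stopifnot(n %% 3L == 0L)
  paste0(chars[seq(1L, n, 3L)], chars[seq(2L, n, 3L)], chars[seq(3L, n, 3L)])
}

## canonical string key for a spliced genomic chain
chainKey <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)[1L]),
        as.character(GenomicRanges::strand(gr)[1L]),
        paste(GenomicRanges::start(gr), GenomicRanges::end(gr),
              sep = "-", collapse = ","),
        sep = ":")
}

## population standard deviation
popSd <- function(x) sqrt(mean((x - mean(x))^2))

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
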