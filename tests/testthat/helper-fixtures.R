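suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(Biostrings)
})

## bind the constructors/accessors used across the test files here, so they
## resolve identically whether the suite runs against the installed package
## or a load_all()ed source tree
GRanges <- GenomicRanges::GRanges
GRangesList <- GenomicRanges::GRangesList
IRanges <- IRanges::IRanges
DataFrame <- S4Vectors::DataFrame
mcols <- S4Vectors::mcols
`mcols<-` <- S4Vectors::`mcols<-`
start <- BiocGenerics::start
end <- BiocGenerics::end
DNAStringSet <- Biostrings::DNAStringSet
AAStringSet <- Biostrings::AAStringSet
readDNAStringSet <- Biostrings::readDNAStringSet

## hand-built TranscriptSet: txs = list of lists with id, gene, biotype,
## strand, exons (matrix/list of c(start, end)), cds (optional), stranded
makeTxSet <- function(txs, chrom = "chr1") {
  info <- do.call(rbind, lapply(txs, function(t) data.frame(
    tx_id = t$id, gene_id = t[["gene"]] %||NA% t$id,
    tx_biotype = t$biotype, gene_biotype = t[["gene_biotype"]] %||NA% t$biotype,
    source_catalog = "test",
    stranded = t[["stranded"]] %||NA% TRUE, stringsAsFactors = FALSE)))
  mk <- function(t, what) {
    iv <- t[[what]]
    if (is.null(iv)) return(GRanges())
    m <- do.call(rbind, iv)
    GRanges(t[["chrom"]] %||NA% chrom, IRanges(m[, 1], m[, 2]),
            strand = t[["strand"]] %||NA% "+")
  }
  exons <- GRangesList(lapply(txs, mk, "exons"))
  cds <- GRangesList(lapply(txs, mk, "cds"))
  names(exons) <- names(cds) <- info$tx_id
  new("TranscriptSet", txinfo = DataFrame(info), exons = exons, cds = cds)
}

`%||NA%` <- function(a, b) if (is.null(a)) b else a

## single-exon plus-strand transcript whose sequence is given; returns
## list(txset, genome) with the transcript at positions (pad+1)..(pad+len)
makeSimpleLocus <- function(seq, id = "tx1", biotype = "lincRNA", pad = 50,
                            chrom = "chr1", stranded = TRUE, cds = NULL) {
  genomeSeq <- paste0(strrep("C", pad), seq, strrep("C", pad))
  tx <- list(id = id, biotype = biotype, stranded = stranded,
             exons = list(c(pad + 1, pad + nchar(seq))))
  if (!is.null(cds)) tx$cds <- lapply(cds, function(x) x + pad)
  ts <- makeTxSet(list(tx), chrom = chrom)
  genome <- DNAStringSet(setNames(genomeSeq, chrom))
  list(txset = ts, genome = genome)
}

## brute-force ORF oracle: enumerate every AUG, walk codons to the first
## in-frame stop, keep the most upstream AUG per stop, apply filters
oracleOrfs <- function(seq, min_nt = 27) {
  n <- nchar(seq)
  found <- list()
  atgs <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (atgs[1L] == -1L) atgs <- integer(0)
  stopsSeen <- character(0)
  for (a in sort(as.integer(atgs))) {
    stopAt <- NA
    p <- a
    while (p + 2 <= n) {
      cod <- substr(seq, p, p + 2)
      if (p > a && cod %in% c("TAA", "TAG", "TGA")) { stopAt <- p; break }
      p <- p + 3
    }
    if (is.na(stopAt)) next
    key <- as.character(stopAt)
    if (key %in% stopsSeen) next           # a more upstream AUG already claimed it
    stopsSeen <- c(stopsSeen, key)
    span <- stopAt + 2 - a + 1
    nt <- substr(seq, a, stopAt + 2)
    if (span < min_nt) next
    if (grepl("N", nt, fixed = TRUE)) next
    found[[length(found) + 1L]] <- data.frame(tx_start = a, tx_end = stopAt + 2,
                                              n_codons = span / 3,
                                              nt_seq = nt, stringsAsFactors = FALSE)
  }
  if (length(found) == 0L)
    return(data.frame(tx_start = integer(0), tx_end = integer(0),
                      n_codons = integer(0), nt_seq = character(0)))
  out <- do.call(rbind, found)
  out[order(out$tx_start, out$tx_end), , drop = FALSE]
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## build a StitchedAlignment directly (for score closed-form tests)
makeStitched <- function(refCodons, rows, coverage = NULL, frameshift = NULL) {
  species <- names(rows)
  n <- length(species)
  if (is.null(coverage)) coverage <- rep(1, n)
  if (is.null(frameshift)) frameshift <- rep(FALSE, n)
  fl <- DataFrame(coverage = coverage, has_frameshift_indel = frameshift,
                  has_premature_stop = rep(FALSE, n),
                  start_conserved = rep(TRUE, n),
                  stop_conserved = rep(TRUE, n),
                  splice_sites_conserved = rep(TRUE, n))
  rownames(fl) <- species
  new("StitchedAlignment", refSpecies = "ref", refCodons = refCodons,
      rows = rows, flags = fl)
}

## small synthetic bundle shared across tests (built once per test run)
smallBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "sorfcons_small_bundle")
      cfg <- simulationConfig(seed = 42L, n_coding = 24L, n_neutral = 24L,
                              n_pseudo = 6L, n_families = 6L)
      cache <<- simulateLocusSet(cfg, dir)
    }
    cache
  }
})

## run the scan->group pipeline on a bundle and match planted ORFs
bundleCatalog <- local({
  cache <- list()
  function(bundle) {
    key <- bundle$paths[["gtf"]]
    if (is.null(cache[[key]])) {
      txset <- readAnnotation(bundle$paths[["gtf"]])
      genome <- readDNAStringSet(bundle$paths[["genome"]])
      names(genome) <- sub(" .*", "", names(genome))
      orfs <- buildOrfCatalog(txset, genome)
      orfs <- classifyOrfs(orfs, txset)
      cache[[key]] <<- list(txset = txset, genome = genome, orfs = orfs)
    }
    cache[[key]]
  }
})

## ids of catalog ORFs matching the planted truth (same tx + tx_start)
matchPlanted <- function(orfs, truth) {
  info <- orfInfo(orfs)
  key <- paste(info$rep_tx, info$tx_start)
  tkey <- paste(truth$tx_id, truth$orf_tx_start)
  ids <- info$orf_id[match(tkey, key)]
  setNames(ids, truth$locus)
}

## build an ORFSet of single-exon plus-strand ORFs from (start, n_codons)
simpleOrfSet <- function(specs, chrom = "chr1", categories = NULL) {
  n <- length(specs)
  ids <- sprintf("o%03d", seq_len(n))
  chains <- lapply(specs, function(s)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s[1], s[1] + 3 * s[2] - 1),
                           strand = "+"))
  rng <- GenomicRanges::GRangesList(chains)
  names(rng) <- ids
  nt <- vapply(specs, function(s)
    paste0("ATG", strrep("GCA", s[2] - 2), "TAA"), character(1))
  aa <- vapply(specs, function(s)
    paste0("M", strrep("A", s[2] - 2)), character(1))
  info <- S4Vectors::DataFrame(
    orf_id = ids, tx_ids = IRanges::CharacterList(as.list(ids)),
    rep_tx = ids, tx_start = 1L,
    tx_end = vapply(specs, function(s) as.integer(3 * s[2]), integer(1)),
    scan_strand = "+",
    n_codons = vapply(specs, function(s) as.integer(s[2]), integer(1)),
    nt_seq = nt, aa_seq = aa,
    category = categories %||NA% rep("lincRNA", n),
    uses_most_upstream_aug = TRUE)
  rownames(info) <- ids
  new("ORFSet", ranges = rng, info = info)
}
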