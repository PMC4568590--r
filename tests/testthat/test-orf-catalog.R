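test_that("scanner applies the length threshold and most-upstream-AUG rule", {
  expect_equal(nrow(scanOrfs("ATGAAATAG")), 0L)            # 9 nt < 27

  hits <- scanOrfs(paste0("ATG", strrep("GCA", 8), "TAA"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_codons, 10L)
  expect_equal(hits$aa_seq, "MAAAAAAAA")

  ## two in-frame AUGs, one stop: ORF starts at the FIRST (most upstream)
  hits2 <- scanOrfs(paste0("ATGATG", strrep("GCA", 8), "TGA"))
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$tx_start, 1L)
  expect_equal(hits2$n_codons, 11L)
})

test_that("ORFs with N in a codon are dropped and truncated ORFs discarded", {
  withN <- paste0("ATG", strrep("GCA", 4), "GNA", strrep("GCA", 3), "TAA")
  expect_equal(nrow(scanOrfs(withN)), 0L)
  noStop <- paste0("ATG", strrep("GCA", 20))
  expect_equal(nrow(scanOrfs(noStop)), 0L)
  expect_error(scanOrfs("ATGXXX"), "alphabet")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(11)
  for (i in 1:60) {
    s <- randomSeq(sample(100:600, 1),
                   alphabet = c("A", "C", "G", "T",
                                if (i %% 5 == 0) "N"))
    got <- scanOrfs(s)
    want <- oracleOrfs(s)
    expect_equal(got[, c("tx_start", "tx_end", "n_codons", "nt_seq")],
                 want, ignore_attr = TRUE)
  }
})

test_that("both-strand scanning reports reverse-complement hits", {
  fwd <- paste0("ATG", strrep("GCA", 8), "TAA")
  s <- revComp(fwd)
  hits <- scanOrfs(s, both_strands = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$scan_strand, "-")
  expect_equal(hits$nt_seq, fwd)
})

test_that("identical ORFs across isoforms are grouped, different phases are not", {
  orf <- paste0("ATG", strrep("GCA", 8), "TAA")
  seqA <- paste0(strrep("C", 12), orf, strrep("C", 9))
  ts <- makeTxSet(list(
    list(id = "tA", biotype = "lincRNA", exons = list(c(101, 100 + nchar(seqA)))),
    list(id = "tB", biotype = "lincRNA", exons = list(c(107, 100 + nchar(seqA))))
  ))
  genome <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("C", 100), seqA, strrep("C", 50)), "chr1"))
  orfs <- buildOrfCatalog(ts, genome)
  expect_equal(length(orfs), 1L)
  expect_setequal(orfInfo(orfs)$tx_ids[[1]], c("tA", "tB"))

  ## same interval chain, different reading phase -> two groups
  h1 <- data.frame(tx_start = 1L, tx_end = 30L, n_codons = 10L,
                   nt_seq = paste0("ATG", strrep("GCA", 8), "TAA"),
                   aa_seq = "MAAAAAAAA", scan_strand = "+", tx_id = "tA")
  h2 <- h1; h2$aa_seq <- "MAAARAAAA"; h2$tx_id <- "tB"
  ts2 <- makeTxSet(list(
    list(id = "tA", biotype = "lincRNA", exons = list(c(101, 130))),
    list(id = "tB", biotype = "lincRNA", exons = list(c(101, 130)))))
  g <- groupOrfs(list(h1, h2), ts2)
  expect_equal(length(g), 2L)

  ## disjoint ORFs do not merge
  h3 <- h1; h3$tx_id <- "tB"
  ts3 <- makeTxSet(list(
    list(id = "tA", biotype = "lincRNA", exons = list(c(101, 130))),
    list(id = "tB", biotype = "lincRNA", exons = list(c(501, 530)))))
  g3 <- groupOrfs(list(h1, h3), ts3)
  expect_equal(length(g3), 2L)
})

test_that("classification follows the fixed category order", {
  orf <- paste0("ATG", strrep("GCA", 8), "TAA")        # 30 nt
  utr <- strrep("C", 30)
  ## coding transcript: CDS = ORF (stop excluded, annotation convention)
  seqs <- paste0(utr, orf, utr)
  txs <- list(
    list(id = "coding", biotype = "protein_coding",
         exons = list(c(101, 100 + nchar(seqs))),
         cds = list(c(131, 157))),
    list(id = "sno", biotype = "snoRNA", chrom = "chr2",
         exons = list(c(101, 100 + nchar(seqs)))),
    list(id = "linc", biotype = "lincRNA", chrom = "chr3",
         exons = list(c(101, 100 + nchar(seqs)))))
  ts <- makeTxSet(txs)
  genome <- Biostrings::DNAStringSet(setNames(
    rep(paste0(strrep("C", 100), seqs, strrep("C", 50)), 3),
    c("chr1", "chr2", "chr3")))
  orfs <- classifyOrfs(buildOrfCatalog(ts, genome), ts)
  cats <- orfCategories(orfs)
  info <- orfInfo(orfs)
  byTx <- setNames(unname(cats), vapply(info$tx_ids, `[[`, "", 1L))
  expect_equal(unname(byTx["coding"]), "annotated")
  expect_equal(unname(byTx["sno"]), "ncRNA")
  expect_equal(unname(byTx["linc"]), "lincRNA")
})

test_that("UTR ORFs, pseudogenes and CDS overlap are classified correctly", {
  orf <- paste0("ATG", strrep("GCA", 8), "TAA")
  cdsSeq <- paste0("ATG", strrep("GAA", 30), "TAA")     # main CDS, 96 nt (no internal ATG)
  ## transcript: 5'UTR ORF | CDS | 3'UTR ORF
  seq <- paste0(strrep("C", 5), orf, strrep("C", 10), cdsSeq,
                strrep("C", 10), orf, strrep("C", 5))
  cdsStart <- 5 + 30 + 10 + 1
  ts <- makeTxSet(list(
    list(id = "m", biotype = "protein_coding",
         exons = list(c(101, 100 + nchar(seq))),
         cds = list(c(100 + cdsStart, 100 + cdsStart + 92))),
    list(id = "psi", biotype = "processed_pseudogene",
         gene_biotype = "processed_pseudogene", chrom = "chr2",
         exons = list(c(101, 140)))))
  g1 <- paste0(strrep("C", 100), seq, strrep("C", 50))
  g2 <- paste0(strrep("C", 100), paste0(orf, strrep("A", 10)), strrep("C", 50))
  genome <- Biostrings::DNAStringSet(setNames(c(g1, g2), c("chr1", "chr2")))
  orfs <- classifyOrfs(buildOrfCatalog(ts, genome), ts)
  info <- orfInfo(orfs)
  cats <- setNames(info$category, paste0(vapply(info$tx_ids, `[[`, "", 1L),
                                         "@", info$tx_start))
  expect_equal(unname(cats[paste0("m@", 6)]), "utr5")
  expect_equal(unname(cats[paste0("m@", 5 + 30 + 10 + 1)]), "annotated")
  expect_equal(unname(cats[paste0("m@", 5 + 30 + 10 + 96 + 10 + 1)]), "utr3")
  expect_equal(unname(cats[grep("psi", names(cats))]), "pseudogene")
})

test_that("every scanned group receives exactly one category", {
  b <- smallBundle()
  cat <- bundleCatalog(b)
  cats <- orfCategories(cat$orfs)
  expect_true(all(!is.na(cats)))
  expect_true(all(cats %in% c("annotated", "pseudogene", "ncRNA", "utr3",
                              "utr5", "cds_overlap", "other", "lincRNA")))
  ## planted ORFs are recovered and carry the expected categories
  planted <- matchPlanted(cat$orfs, b$truth)
  expect_true(all(!is.na(planted)))
  byClass <- split(unname(cats[planted]), b$truth$biotype)
  expect_true(all(byClass$protein_coding == "annotated"))
  expect_true(all(byClass$snoRNA == "ncRNA"))
  expect_true(all(byClass$processed_pseudogene == "pseudogene"))
  expect_true(all(byClass$lincRNA == "lincRNA"))
})
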