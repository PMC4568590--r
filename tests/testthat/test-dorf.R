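## host mRNA with a dORF in its 3'UTR, on a conservation step track
dorfFixture <- function(gapCodons = c("CCC", "TGA", "CCC", "CCC", "CCC",
                                      "CCC", "CCC", "CCC", "CCC", "CCC"),
                        inHigh = 1.0, outLow = 0.2) {
  cds <- paste0("ATG", strrep("GAA", 30), "TAA")            # 96 nt
  gap <- paste(gapCodons, collapse = "")                    # in CDS frame
  dorf <- paste0("ATG", strrep("GCA", 8), "TAA")            # 30 nt
  seq <- paste0(strrep("C", 40), cds, gap, dorf, strrep("C", 40))
  cdsStart <- 41
  cdsEnd <- cdsStart + 93 - 1                               # stop excluded
  loc <- makeSimpleLocus(seq, biotype = "protein_coding",
                         cds = list(c(cdsStart, cdsEnd)))
  orfs <- classifyOrfs(buildOrfCatalog(loc$txset, loc$genome), loc$txset)
  ## step track: high inside the CDS, low after its stop codon
  pad <- 50
  stopEnd <- pad + cdsEnd + 3                               # genomic end of stop
  gr <- GRanges("chr1", IRanges(c(1, stopEnd + 1),
                                c(stopEnd, pad + nchar(seq) + pad)),
                score = c(inHigh, outLow))
  track <- conservationTrack(gr)
  dorfStartTx <- 40 + 96 + nchar(gap) + 1
  list(loc = loc, orfs = orfs, track = track, cdsStartTx = cdsStart,
       dorfStartTx = dorfStartTx, gapLen = nchar(gap))
}

test_that("stop step is inside-minus-outside with the stop codon excluded", {
  fx <- dorfFixture()
  ss <- stopStep(fx$loc$txset, "tx1", fx$track)
  expect_equal(ss$step, 0.8)
  expect_equal(ss$inside, 1.0)
  expect_equal(ss$outside, 0.2)
  ## flat track -> 0; inverted track -> negative
  flat <- conservationTrack(GRanges("chr1", IRanges(1, 500), score = 0.5))
  expect_equal(stopStep(fx$loc$txset, "tx1", flat)$step, 0)
  fx2 <- dorfFixture(inHigh = 0.2, outLow = 1.0)
  expect_equal(stopStep(fx2$loc$txset, "tx1", fx2$track)$step, -0.8)
})

test_that("dORF statistics: distance, frame, intervening stops, overlap", {
  fx <- dorfFixture()
  info <- orfInfo(fx$orfs)
  dorfId <- info$orf_id[info$tx_start == fx$dorfStartTx]
  expect_equal(unname(orfCategories(fx$orfs)[dorfId]), "utr3")
  seqs <- transcriptSeqs(fx$loc$txset, fx$loc$genome)
  st <- dorfStats(fx$orfs, dorfId, fx$loc$txset, seqs, fx$track)
  expect_equal(st$distance_to_cds_stop, fx$gapLen)
  ## gap is a whole number of codons -> same frame as the CDS
  expect_equal(st$frame_offset, 0L)
  expect_equal(st$n_intervening_stops, 1L)       # one TGA in the gap
  expect_false(st$overlaps_annotated_cds)
  expect_equal(st$stop_step, 0.8)

  ## dORF 30 nt downstream in the same frame: distance 30, offset 0
  fx30 <- dorfFixture(gapCodons = rep("CCC", 10))
  info30 <- orfInfo(fx30$orfs)
  d30 <- info30$orf_id[info30$tx_start == fx30$dorfStartTx]
  st30 <- dorfStats(fx30$orfs, d30, fx30$loc$txset,
                    transcriptSeqs(fx30$loc$txset, fx30$loc$genome), fx30$track)
  expect_equal(st30$distance_to_cds_stop, 30L)
  expect_equal(st30$frame_offset, 0L)
  expect_equal(st30$n_intervening_stops, 0L)

  ## frame shifts by the gap length mod 3
  fxShift <- dorfFixture(gapCodons = c(rep("CCC", 9), "CC"))
  infoS <- orfInfo(fxShift$orfs)
  dS <- infoS$orf_id[infoS$tx_start == fxShift$dorfStartTx]
  stS <- dorfStats(fxShift$orfs, dS, fxShift$loc$txset,
                   transcriptSeqs(fxShift$loc$txset, fxShift$loc$genome),
                   fxShift$track)
  expect_equal(stS$frame_offset, 2L)

  ## an upstream dORF errors
  uorfId <- info$orf_id[info$tx_start < fx$cdsStartTx]
  if (length(uorfId))
    expect_error(dorfStats(fx$orfs, uorfId[1], fx$loc$txset, seqs, fx$track),
                 "downstream")
})

test_that("frame offset is invariant under intron insertion in spliced coordinates", {
  ## same transcript sequence, with and without an intron inside the gap
  cds <- paste0("ATG", strrep("GAA", 10), "TAA")
  gap <- strrep("CCC", 4)
  dorf <- paste0("ATG", strrep("GCA", 8), "TAA")
  plain <- makeSimpleLocus(paste0(strrep("C", 10), cds, gap, dorf,
                                  strrep("C", 10)),
                           biotype = "protein_coding",
                           cds = list(c(11, 11 + nchar(cds) - 4)))
  ## spliced version: 100-nt intron splits the gap (genomic coordinates)
  pre <- paste0(strrep("C", 10), cds, strrep("CCC", 2))
  post <- paste0(strrep("CCC", 2), dorf, strrep("C", 10))
  gseq <- paste0(pre, strrep("T", 100), post)
  ts <- makeTxSet(list(list(
    id = "tx1", biotype = "protein_coding",
    exons = list(c(1, nchar(pre)), c(nchar(pre) + 101, nchar(gseq))),
    cds = list(c(11, 11 + nchar(cds) - 4)))))
  genome <- Biostrings::DNAStringSet(setNames(gseq, "chr1"))
  track <- conservationTrack(GRanges("chr1", IRanges(1, nchar(gseq) + 200),
                                     score = 0.5))
  get1 <- function(txset, g) {
    orfs <- classifyOrfs(buildOrfCatalog(txset, g), txset)
    info <- orfInfo(orfs)
    id <- info$orf_id[orfCategories(orfs) == "utr3"]
    dorfStats(orfs, id[1], txset, transcriptSeqs(txset, g), track)
  }
  a <- get1(plain$txset, plain$genome)
  b <- get1(ts, genome)
  expect_equal(a$frame_offset, b$frame_offset)
  expect_equal(a$distance_to_cds_stop, b$distance_to_cds_stop)
})

test_that("readthrough matching is exact on stop-codon coordinates", {
  fx <- dorfFixture()
  stops <- orfStopCoords(fx$orfs)
  hit <- stops[1, ]
  expect_equal(matchReadthrough(stops, hit), stops$id[1])
  shifted <- transform(hit, start = start + 3, end = end + 3)
  expect_length(matchReadthrough(stops, shifted), 0L)
  empty <- hit[0, ]
  expect_length(matchReadthrough(stops, empty), 0L)
})
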