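## one single-exon plus-strand ORF with a hand-built alignment block
featFixture <- function(rowsFun, ins = list()) {
  orf <- paste0("ATG", strrep("GCA", 8), "TAA")          # 30 nt
  loc <- makeSimpleLocus(paste0(strrep("C", 30), orf, strrep("C", 30)))
  orfs <- buildOrfCatalog(loc$txset, loc$genome)
  chain <- orfRanges(orfs)[[1]]
  gs <- start(chain); ge <- end(chain)
  refRow <- as.character(loc$genome[[1]])
  refRow <- substr(refRow, gs, ge)
  rows <- rowsFun(refRow)
  blocks <- list(list(chrom = "chr1", start = gs, end = ge, ref = "ref",
                      rows = c(ref = refRow, rows), ins = ins))
  list(orfs = orfs, blocks = blocks, gs = gs, ge = ge)
}

test_that("stitching computes coverage and frameshift flags from raw blocks", {
  fx <- featFixture(function(ref) c(spA = ref))
  st <- stitchAndFlag(fx$orfs, orfIds(fx$orfs)[1], fx$blocks)
  expect_s4_class(st, "StitchedAlignment")
  expect_equal(st@flags["spA", "coverage"], 1.0)
  expect_false(st@flags["spA", "has_frameshift_indel"])
  expect_true(st@flags["spA", "start_conserved"])
  expect_true(st@flags["spA", "stop_conserved"])

  ## 1-nt insertion inside the ORF: frameshifting (1 mod 3 != 0)
  fx2 <- featFixture(function(ref) c(spA = ref),
                     ins = list(spA = data.frame(pos = 95, len = 1)))
  st2 <- stitchAndFlag(fx2$orfs, orfIds(fx2$orfs)[1], fx2$blocks)
  expect_true(st2@flags["spA", "has_frameshift_indel"])

  ## 3-nt deletion: NOT frameshifting
  fx3 <- featFixture(function(ref) {
    r <- ref
    substr(r, 10, 12) <- "---"
    c(spA = r)
  })
  st3 <- stitchAndFlag(fx3$orfs, orfIds(fx3$orfs)[1], fx3$blocks)
  expect_false(st3@flags["spA", "has_frameshift_indel"])

  ## 2-nt deletion: frameshifting
  fx4 <- featFixture(function(ref) {
    r <- ref
    substr(r, 10, 11) <- "--"
    c(spA = r)
  })
  st4 <- stitchAndFlag(fx4$orfs, orfIds(fx4$orfs)[1], fx4$blocks)
  expect_true(st4@flags["spA", "has_frameshift_indel"])
})

test_that("no blocks give zero species; premature stops are flagged", {
  fx <- featFixture(function(ref) c(spA = ref))
  st <- stitchAndFlag(fx$orfs, orfIds(fx$orfs)[1], list())
  expect_equal(length(st@rows), 0L)
  expect_equal(frameConservationCount(st), 0L)
  expect_equal(selectionScore(st), 0)               # empty sum

  fxStop <- featFixture(function(ref) {
    r <- ref
    substr(r, 4, 6) <- "TAA"                         # codon 2 -> stop
    c(spA = r)
  })
  st2 <- stitchAndFlag(fxStop$orfs, orfIds(fxStop$orfs)[1], fxStop$blocks)
  expect_true(st2@flags["spA", "has_premature_stop"])
})

test_that("frame conservation counts species with coverage >= 0.5 and no frameshift", {
  rows <- c(clean1 = strrep("A", 30), clean2 = strrep("A", 30),
            shifted = strrep("A", 30), lowcov = paste0(strrep("-", 21), strrep("A", 9)))
  st <- makeStitched(splitCodons(paste0("ATG", strrep("GCA", 8), "TAA")),
                     rows, coverage = c(1, 1, 1, 0.3),
                     frameshift = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(frameConservationCount(st), 2L)
  st5 <- makeStitched(splitCodons(paste0("ATG", strrep("GCA", 8), "TAA")),
                      setNames(rep(strrep("A", 30), 5), paste0("s", 1:5)))
  expect_equal(frameConservationCount(st5), 5L)
})

test_that("surrogate selection score matches closed forms", {
  ## 10 identical sense codons, 1 species
  refCod <- rep("GCA", 10)
  st <- makeStitched(refCod, c(spA = strrep("GCA", 10)))
  expect_equal(selectionScore(st), 10 * log2(0.55 / 0.40), tolerance = 1e-12)
  expect_equal(10 * log2(0.55 / 0.40), 4.594, tolerance = 1e-3)

  ## one nonsynonymous event: GCA (Ala) -> GAA (Glu)
  st2 <- makeStitched(refCod, c(spA = paste0("GAA", strrep("GCA", 9))))
  expect_equal(selectionScore(st2),
               9 * log2(0.55 / 0.40) + log2(0.14 / 0.35), tolerance = 1e-12)
  expect_equal(log2(0.14 / 0.35), -1.322, tolerance = 1e-3)

  ## synonymous and stop-introducing events
  st3 <- makeStitched(rep("GCA", 2), c(spA = "GCGTGA"))   # syn + stop
  expect_equal(selectionScore(st3),
               log2(0.30 / 0.20) + log2(0.01 / 0.05), tolerance = 1e-12)

  ## frameshifted or low-coverage species are excluded
  st4 <- makeStitched(refCod, c(spA = strrep("GCA", 10)), frameshift = TRUE)
  expect_equal(selectionScore(st4), 0)
  ## gap codons are skipped
  st5 <- makeStitched(refCod, c(spA = paste0("---", strrep("GCA", 9))))
  expect_equal(selectionScore(st5), 9 * log2(0.55 / 0.40), tolerance = 1e-12)
})

test_that("table backend looks up scores and reports missing ids", {
  tab <- c(orf1 = 3.5, orf2 = -1)
  expect_equal(selectionScore(backend = "table", scores = tab,
                              orf_id = c("orf2", "orf1")), c(-1, 3.5))
  expect_error(selectionScore(backend = "table", scores = tab,
                              orf_id = c("orf1", "orfX")), "orfX")
})

test_that("step profile distances follow the Euclidean closed forms", {
  expect_equal(stepProfileDistance(rep(0.4, 50), rep(0.4, 50)), 0)
  expect_equal(stepProfileDistance(rep(0, 50), rep(1, 50)), sqrt(50))
  expect_equal(sqrt(50), 7.071, tolerance = 1e-3)
  ## mean profile of a single-ORF set equals that ORF's profile
  m <- matrix(runif(50), 1, 50, dimnames = list("o1", NULL))
  expect_equal(buildMeanProfile(m), unname(m[1, ]), ignore_attr = TRUE)
  ## clipped windows rescale to the 50-base equivalent
  p <- c(rep(NA, 25), rep(0, 25))
  expect_equal(stepProfileDistance(p, rep(1, 50)), sqrt(25) * sqrt(50 / 25))
})

test_that("ORF step profiles pick up the planted conservation step", {
  b <- smallBundle()
  cat <- bundleCatalog(b)
  track <- readConservationTrack(b$paths[["track"]])
  planted <- matchPlanted(cat$orfs, b$truth)
  sub <- cat$orfs[planted]
  prof <- orfStepProfiles(sub, cat$txset, track)
  coding <- b$truth$class == "coding_like"
  mStart <- prof$start[planted[coding][1], ]
  ## 0.2 outside the ORF, 0.9 inside: step at the window midpoint
  expect_equal(unname(mStart[1:25]), rep(0.2, 25))
  expect_equal(unname(mStart[26:50]), rep(0.9, 25))
  mStop <- prof$stop[planted[coding][1], ]
  expect_equal(unname(mStop[1:25]), rep(0.9, 25))
  expect_equal(unname(mStop[26:50]), rep(0.2, 25))
  ## neutral loci are flat
  flat <- prof$start[planted[b$truth$class == "neutral"][1], ]
  expect_equal(unname(flat), rep(0.2, 50))
})

test_that("conserving species and MRCA fractions behave on the tree", {
  tree <- ape::read.tree(text = "(((ref:1,sister:1):1,mid:2):1,out:3);")
  sets <- list(c("ref"), c("ref", "sister"), c("ref", "sister", "mid"),
               c("ref", "sister", "mid", "out"))
  mc <- mrcaConservation(sets, tree, "ref")
  expect_equal(mc$fraction[1], 1)                      # leaf: everything
  expect_true(all(diff(mc$fraction) <= 0))             # non-increasing with age
  expect_equal(mc$fraction[length(mc$fraction)], 0.25) # only the full set reaches the root
  ## MRCA of {ref, sister} is the ref-sister ancestor (age rank 2)
  mc2 <- mrcaConservation(list(c("ref", "sister")), tree, "ref")
  expect_equal(mc2$fraction, c(1, 1, 0, 0))
  expect_error(mrcaConservation(list(c("ref", "alien")), tree, "ref"),
               "alien")
})

test_that("conservingSpecies applies start/stop/splice/indel criteria", {
  rows <- c(good = strrep("A", 30), bad = strrep("A", 30))
  st <- makeStitched(splitCodons(paste0("ATG", strrep("GCA", 8), "TAA")), rows)
  st@flags["bad", "start_conserved"] <- FALSE
  expect_setequal(conservingSpecies(st), c("ref", "good"))
  st@flags["good", "has_premature_stop"] <- TRUE
  expect_equal(conservingSpecies(st), "ref")
})
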