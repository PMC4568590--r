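test_that("adjusted scores are z-scores within length bins", {
  ## single bin, population sd
  z <- adjustedScores(c(1, 2, 3), c(10, 10, 10), n_bins = 1)
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(max(abs(z)), 1.225, tolerance = 1e-3)
  ## score equal to its bin mean -> 0
  expect_equal(adjustedScores(c(4, 4, 4), c(1, 2, 3))[1], 0)
  ## rank preservation within a bin
  set.seed(2)
  x <- rnorm(200); len <- sample(9:101, 200, replace = TRUE)
  z2 <- adjustedScores(x, len, n_bins = 5, min_bin = 20)
  br <- quantile(len, seq(0, 1, length.out = 6))
  bin <- cut(len, unique(br), include.lowest = TRUE)
  for (b in levels(bin)) {
    i <- bin == b
    if (sum(i) > 1) expect_equal(order(x[i]), order(z2[i]))
  }
})

test_that("codon site counts follow equal-weight enumeration", {
  tt <- codonSites("TTT")
  expect_equal(tt$s_sites, 1 / 3)
  expect_equal(tt$n_sites, 8 / 3)
  ## independent spot checks against direct enumeration
  enum <- function(cod) {
    gc <- Biostrings::GENETIC_CODE
    syn <- 0
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
      mut <- cod; substr(mut, p, p) <- nt
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[cod]]) syn <- syn + 1
    }
    syn / 3
  }
  for (cod in c("CTG", "ATG", "TGG", "GGG", "AGA")) {
    expect_equal(codonSites(cod)$s_sites, enum(cod), info = cod)
  }
  expect_equal(codonSites(c("TTT", "TTT"))$s_sites, c(1, 1) / 3)
  expect_error(codonSites("XYZ"), "invalid codon")
})

test_that("dN/dS arithmetic, filters and degenerate cases", {
  ## hand-placed SNPs on one 11-codon ORF
  orf <- paste0("ATG", strrep("TTT", 9), "TAA")       # 33 nt
  loc <- makeSimpleLocus(paste0(strrep("C", 9), orf, strrep("C", 9)))
  orfs <- buildOrfCatalog(loc$txset, loc$genome)
  gs <- start(orfRanges(orfs)[[1]])                   # genomic ORF start
  mkv <- function(pos, ref, alt, daf = 0.2, strand = "+", inrep = FALSE) {
    gr <- GRanges("chr1", IRanges(pos, pos))
    mcols(gr) <- DataFrame(ref = ref, alt = alt, daf = daf,
                           snp_strand = strand, in_repeat = inrep)
    gr
  }
  ## codon 2 (TTT): pos3 T->C synonymous; codon 3 pos1 T->A nonsynonymous
  v <- c(mkv(gs + 5, "T", "C"), mkv(gs + 6, "T", "A"))
  res <- snpDnds(orfs, v)
  expect_equal(res$n_syn, 1L)
  expect_equal(res$n_nonsyn, 1L)
  expect_equal(res$s_sites, 9 * 1 / 3)
  expect_equal(res$n_sites, 9 * 8 / 3)
  expect_equal(res$dnds, (1 / 24) / (1 / 3), tolerance = 1e-12)
  ## worked arithmetic from counts
  expect_equal((1 / 30) / (2 / 10), 0.1667, tolerance = 1e-3)

  ## filters: rare DAF, repeat and minus-strand SNPs are excluded
  vf <- c(mkv(gs + 5, "T", "C", daf = 0.005),
          mkv(gs + 8, "T", "C", inrep = TRUE),
          mkv(gs + 11, "T", "C", strand = "-"),
          mkv(gs + 6, "T", "A"))
  resf <- snpDnds(orfs, vf)
  expect_equal(resf$n_syn, 0L)
  expect_equal(resf$n_nonsyn, 1L)
  expect_true(resf$undefined)
  expect_equal(resf$dnds, Inf)

  ## SNPs in start/stop codons are not counted
  vs <- mkv(gs + 1, "T", "C")
  expect_equal(snpDnds(orfs, vs)$n_syn + snpDnds(orfs, vs)$n_nonsyn, 0L)
})

test_that("reciprocal chi-squared test reports the larger one-sided P", {
  cand <- list(n_syn = 40L, n_nonsyn = 10L, s_sites = 10, n_sites = 30)
  ctrl <- list(n_syn = 24L, n_nonsyn = 72L, s_sites = 10, n_sites = 30)
  rt <- reciprocalDndsTest(cand, ctrl)
  expect_equal(rt$p, max(rt$p_cand, rt$p_ctrl))
  expect_lt(rt$p_cand, 0.05)       # strong depletion
  expect_gte(rt$p_ctrl, 0.5)       # control exactly at expectation
})

test_that("matched controls pass the rank-test criterion on matchable pools", {
  set.seed(31)
  candCons <- setNames(runif(40, 0.4, 0.6), sprintf("c%02d", 1:40))
  poolCons <- setNames(runif(400, 0.2, 0.8), sprintf("p%03d", 1:400))
  poolScores <- setNames(rnorm(400, 0, 5), names(poolCons))
  ctrl <- selectMatchedControls(candCons, poolCons, poolScores, seed = 4)
  expect_gt(attr(ctrl, "p_value"), 0.1)
  ## controls come from the low-|score| window
  expect_true(all(abs(poolScores[ctrl]) <=
                    quantile(abs(poolScores), 0.2) + 1e-12))
  ## pool identical to candidates: trivially matched
  ctrl2 <- selectMatchedControls(candCons, candCons,
                                 setNames(rep(0, 40), names(candCons)), seed = 1)
  expect_gt(attr(ctrl2, "p_value"), 0.1)
  ## infeasible matching errors with the achieved P
  flat <- setNames(rep(0, 100), sprintf("f%03d", 1:100))
  hi <- setNames(rep(0.9, 40), sprintf("c%02d", 1:40))
  expect_error(selectMatchedControls(hi, flat, setNames(rep(0, 100), names(flat)),
                                     seed = 1, max_attempts = 20),
               "infeasible")
})

test_that("simulated SNPs recover the planted omega", {
  set.seed(99)
  b <- smallBundle()
  plant <- b$orfset
  coding <- b$truth$class == "coding_like"
  est02 <- replicate(8, {
    v <- simulateSnps(plant, omega = 0.2, snp_per_kb = 25,
                      ids = orfIds(plant)[coding])
    snpDnds(plant, v, ids = orfIds(plant)[coding])$dnds
  })
  expect_true(mean(est02 >= 0.15 & est02 <= 0.25) >= 0.85)
  v1 <- simulateSnps(plant, omega = 1, snp_per_kb = 25,
                     ids = orfIds(plant)[!coding])
  est1 <- snpDnds(plant, v1, ids = orfIds(plant)[!coding])$dnds
  expect_gt(est1, 0.8)
  expect_lt(est1, 1.25)
})
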