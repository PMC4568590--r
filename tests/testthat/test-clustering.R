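test_that("PID_eff and the dynamic cutoff match their formulas", {
  expect_equal(pidEff(100, 20, 20), 100)            # identical full-length pair
  expect_equal(dynamicCutoff(0, 0), 100)            # 30 + 70 * exp(0)
  expect_equal(dynamicCutoff(10, 10), 30 + 70 * exp(-1))
  expect_equal(dynamicCutoff(10, 10), 55.75, tolerance = 1e-3)
  expect_equal(pidEff(80, 15, 20), 60)
  expect_error(pidEff(50, 10, 0), "positive")
})

## hit table builder: one row per directed hit
mkHits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               percent_identity = as.numeric(r[[3]]),
               alignment_length = as.numeric(r[[4]]),
               e_value = as.numeric(r[[5]]),
               query_length = as.numeric(r[[6]]),
               subject_length = as.numeric(r[[7]]), stringsAsFactors = FALSE)))
}

test_that("graph construction enforces size, E-value and reciprocity rules", {
  species <- c(a1 = "hs", b1 = "mm", c1 = "dr", d1 = "hs")
  ## reciprocal near-identical trio -> one 3-member cluster
  full <- function(q, s, l) list(q, s, 95, l, 1e-9, l, l)
  hits <- mkHits(full("a1", "b1", 30), full("b1", "a1", 30),
                 full("a1", "c1", 30), full("c1", "a1", 30),
                 full("b1", "c1", 30), full("c1", "b1", 30))
  cg <- buildClusterGraph(hits, species)
  expect_length(cg$clusters, 1L)
  expect_setequal(cg$clusters[[1]], c("a1", "b1", "c1"))

  ## 20 vs 26 aa: 23% deviation -> no edge regardless of PID
  hits2 <- mkHits(list("a1", "b1", 100, 20, 1e-9, 20, 26),
                  list("b1", "a1", 100, 20, 1e-9, 26, 20))
  expect_length(buildClusterGraph(hits2, species)$clusters, 0L)

  ## one-directional hit only -> no edge
  hits3 <- mkHits(full("a1", "b1", 30))
  expect_length(buildClusterGraph(hits3, species)$clusters, 0L)

  ## E-value at/above 10 rejected
  hits4 <- mkHits(list("a1", "b1", 95, 30, 10, 30, 30),
                  list("b1", "a1", 95, 30, 10, 30, 30))
  expect_length(buildClusterGraph(hits4, species)$clusters, 0L)

  ## order invariance
  cgRev <- buildClusterGraph(hits[nrow(hits):1, ], species)
  expect_equal(lapply(cg$clusters, sort), lapply(cgRev$clusters, sort))
})

test_that("within-species paralog clusters join across species by RBH only", {
  species <- c(p1 = "hs", p2 = "hs", m1 = "mm", m2 = "mm")
  full <- function(q, s, pid = 95) list(q, s, pid, 30, 1e-9, 30, 30)
  hits <- mkHits(
    full("p1", "p2"), full("p2", "p1"),            # hs paralogs
    full("m1", "m2"), full("m2", "m1"),            # mm paralogs
    full("p1", "m1", 90), full("m1", "p1", 90),    # best cross pair
    full("p2", "m2", 70), full("m2", "p2", 70))    # weaker cross pair
  cg <- buildClusterGraph(hits, species)
  expect_length(cg$clusters, 1L)
  expect_setequal(cg$clusters[[1]], names(species))
})

test_that("isomorphic clusters collapse with multiplicity and report filter", {
  species <- c(h1 = "hs", m1 = "mm", h2 = "hs", m2 = "mm",
               h3 = "hs", f3 = "dr", h4 = "hs", h5 = "hs")
  categories <- c(h1 = "utr5", m1 = "utr5", h2 = "utr5", m2 = "utr5",
                  h3 = "lincRNA", f3 = "lincRNA",
                  h4 = "annotated", h5 = "annotated")
  full <- function(q, s) list(q, s, 95, 30, 1e-9, 30, 30)
  hits <- mkHits(full("h1", "m1"), full("m1", "h1"),
                 full("h2", "m2"), full("m2", "h2"),
                 full("h3", "f3"), full("f3", "h3"),
                 full("h4", "h5"), full("h5", "h4"))
  cg <- buildClusterGraph(hits, species, categories)
  col <- collapseIsomorphic(cg)
  ## two identical {hs:utr5, mm:utr5} clusters merge with multiplicity 2
  expect_equal(sum(col$multiplicity), 4L)
  m2row <- col[col$multiplicity == 2L, ]
  expect_equal(nrow(m2row), 1L)
  expect_true(m2row$reported)
  ## {hs,dr} lincRNA differs from {hs,mm} utr5
  expect_gte(nrow(col), 3L)
  ## single-species annotated paralog cluster excluded from the report
  parRow <- col[grepl("annotated", col$signature), ]
  expect_false(any(parRow$reported))
})

test_that("toy aligner + graph recover planted families exactly", {
  b <- smallBundle()
  pep <- b$peptides
  fam <- pep[!is.na(pep$family), ]
  seqs <- setNames(Biostrings::AAStringSet(pep$aa_seq), pep$id)
  hits <- alignPeptides(seqs, seqs)
  cg <- buildClusterGraph(hits, setNames(pep$species, pep$id),
                          setNames(pep$category, pep$id))
  memb <- rep(names(cg$clusters), lengths(cg$clusters))
  names(memb) <- unlist(cg$clusters)
  got <- memb[fam$id]
  expect_true(all(!is.na(got)))
  expect_equal(mclust::adjustedRandIndex(got, fam$family), 1.0)
})
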