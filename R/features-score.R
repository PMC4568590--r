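#' Codon-level selection score
#'
#' Scores depletion of non-synonymous change over a stitched alignment.
#' With `backend = "surrogate"` the score is computed internally: over all
#' qualifying species (coverage >= 0.5, no frameshifting indel) and all
#' gap-free, `N`-free codon columns whose reference codon is not a stop,
#' the species codon is classified against the reference codon as
#' `identical`, `synonymous`, `nonsynonymous` or `stop_introducing`, and
#' the score is the sum of `log2(P_cod(event) / P_nc(event))`. The default
#' probability tables are package defaults chosen so that coding-like and
#' neutrally evolving sequences separate; they are configurable. With
#' `backend = "table"` precomputed per-ORF scores (e.g. phyloCSF output)
#' are looked up instead.
#'
#' @param stitched a [StitchedAlignment] (surrogate backend).
#' @param backend `"surrogate"` or `"table"`.
#' @param p_cod,p_nc event probabilities under the coding and non-coding
#'   model, in the order (identical, synonymous, nonsynonymous,
#'   stop_introducing).
#' @param scores named numeric vector of precomputed scores (table backend).
#' @param orf_id ORF id(s) to look up (table backend).
#' @param min_coverage species qualification threshold.
#' @return numeric score (0 for an alignment with no qualifying species).
#' @export
selectionScore <- function(stitched = NULL, backend = c("surrogate", "table"),
                           p_cod = c(0.55, 0.30, 0.14, 0.01),
                           p_nc = c(0.40, 0.20, 0.35, 0.05),
                           scores = NULL, orf_id = NULL, min_coverage = 0.5) {
  backend <- match.arg(backend)
  if (backend == "table") {
    if (is.null(scores) || is.null(orf_id))
      stop("table backend needs 'scores' and 'orf_id'")
    missing <- orf_id[!orf_id %in% names(scores)]
    if (length(missing))
      stop("no precomputed score for ORF(s): ", paste(missing, collapse = ", "))
    return(unname(scores[orf_id]))
  }
  stopifnot(is(stitched, "StitchedAlignment"))
  lr <- log2(p_cod / p_nc)
  fl <- stitched@flags
  qualify <- rownames(fl)[fl$coverage >= min_coverage & !fl$has_frameshift_indel]
  if (length(qualify) == 0L) return(0)
  refCod <- stitched@refCodons
  use <- !refCod %in% STOP_CODONS
  refAa <- translateCodons(refCod)
  total <- 0
  for (sp in qualify) {
    cod <- chunkCodons(strsplit(stitched@rows[[sp]], "", fixed = TRUE)[[1L]])
    clean <- use & !grepl("[-N.]", cod)
    if (!any(clean)) next
    ev <- integer(sum(clean))
    sc <- cod[clean]; rc <- refCod[clean]; ra <- refAa[clean]
    sa <- translateCodons(sc)
    ev[] <- 3L                               # nonsynonymous
    ev[sa == "*"] <- 4L                      # stop-introducing
    ev[sa == ra & sa != "*"] <- 2L           # synonymous
    ev[sc == rc] <- 1L                       # identical
    total <- total + sum(lr[ev])
  }
  total
}

#' Conservation step profiles around ORF boundaries
#'
#' Extracts per-base conservation in fixed 50-nt windows anchored at the
#' ORF's start codon (25 nt upstream + first 25 nt of the ORF) and at its
#' stop (last 25 nt of the ORF + 25 nt downstream), in spliced transcript
#' coordinates, extending into flanking genomic sequence where the window
#' leaves the transcript. Windows clipped at a contig edge keep the
#' available bases; [stepProfileDistance()] rescales for them.
#'
#' @param orfset an [ORFSet].
#' @param txset the host [TranscriptSet].
#' @param track a [ConservationTrack].
#' @param half half-window size in nt (25 gives the 50-nt windows).
#' @return list of two numeric matrices `start` and `stop` (ORFs x 2*half),
#'   `NA` marking clipped positions.
#' @export
orfStepProfiles <- function(orfset, txset, track, half = 25L) {
  ids <- orfIds(orfset)
  w <- 2L * half
  startM <- stopM <- matrix(NA_real_, length(ids), w, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    rec <- orfset@info[i, ]
    ex <- txset@exons[[rec$rep_tx]]
    strand <- exonStrand(ex)
    if (rec$scan_strand == "-") strand <- flipStrand(strand)
    chrom <- as.character(GenomicRanges::seqnames(ex)[1L])
    pos <- txPositionsExtended(ex, strand, half, half)
    s1 <- rec$tx_start + half                # index of ATG in extended coords
    e1 <- rec$tx_end + half                  # index of last stop-codon base
    wStart <- seq(s1 - half, s1 + half - 1L)
    wStop <- seq(e1 - half + 1L, e1 + half)
    ok1 <- wStart >= 1L & wStart <= length(pos) & pos[pmax(wStart, 1L)] >= 1L
    ok2 <- wStop >= 1L & wStop <= length(pos) & pos[pmin(wStop, length(pos))] >= 1L
    startM[i, ok1] <- trackValues(track, chrom, pos[wStart[ok1]])
    stopM[i, ok2] <- trackValues(track, chrom, pos[wStop[ok2]])
  }
  list(start = startM, stop = stopM)
}

#' Base-wise mean profile over a training set
#'
#' @param profiles matrix from [orfStepProfiles()] (one anchor).
#' @return numeric vector of column means (`NA` positions ignored).
#' @export
buildMeanProfile <- function(profiles) {
  colMeans(profiles, na.rm = TRUE)
}

#' Euclidean distance of a step profile from the positive-set mean
#'
#' Clipped (NA) positions are dropped from both vectors and the distance is
#' rescaled by `sqrt(width / observed)` to a full-window equivalent.
#'
#' @param profile numeric vector (one ORF, one anchor).
#' @param mean_profile vector from [buildMeanProfile()].
#' @return numeric distance (>= 0).
#' @export
stepProfileDistance <- function(profile, mean_profile) {
  stopifnot(length(profile) == length(mean_profile))
  ok <- !is.na(profile) & !is.na(mean_profile)
  if (!any(ok)) return(NA_real_)
  d <- sqrt(sum((profile[ok] - mean_profile[ok])^2))
  d * sqrt(length(profile) / sum(ok))
}

#' Ancestral conservation from conserving species sets
#'
#' For each ORF the most recent common ancestor (MRCA) of the set of
#' conserving species (reference included) is located on the species tree;
#' per ancestor along the reference lineage the fraction of ORFs whose MRCA
#' is at least that old is reported. Fractions are monotonically
#' non-increasing with ancestor age.
#'
#' @param species_sets list of character vectors from [conservingSpecies()].
#' @param tree rooted `phylo` species tree.
#' @param ref reference species (a tree leaf).
#' @return a data.frame with one row per ancestor on the reference lineage
#'   (leaf first): `node`, `age_rank` and `fraction`.
#' @export
mrcaConservation <- function(species_sets, tree, ref) {
  leaves <- tree$tip.label
  allsp <- unique(unlist(species_sets))
  missing <- setdiff(allsp, leaves)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (!ref %in% leaves) stop("reference not in tree: ", ref)
  refTip <- match(ref, leaves)
  ## path from reference leaf to the root (each node = one ancestor age)
  path <- refTip
  node <- refTip
  parent <- function(n) tree$edge[tree$edge[, 2L] == n, 1L]
  repeat {
    p <- parent(node)
    if (length(p) == 0L) break
    path <- c(path, p)
    node <- p
  }
  mrcaNode <- vapply(species_sets, function(set) {
    set <- unique(c(set, ref))
    if (length(set) == 1L) return(refTip)
    ape::getMRCA(tree, set)
  }, numeric(1))
  rank <- match(mrcaNode, path)
  if (anyNA(rank))
    stop("MRCA off the reference lineage; is the tree rooted?")
  data.frame(node = path, age_rank = seq_along(path),
             fraction = vapply(seq_along(path),
                               function(k) mean(rank >= k), numeric(1)))
}
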