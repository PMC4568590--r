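#' Amino-acid and codon usage of a group of ORFs
#'
#' Counts amino-acid usage over the encoded peptides, excluding the start
#' (initiator methionine) and the stop, and per-amino-acid codon
#' distributions from the nucleotide sequences.
#'
#' @param aa_seqs character vector of peptide sequences (no stop symbol).
#' @param nt_seqs optional parallel nucleotide sequences (ATG..stop) for
#'   codon usage.
#' @return list with `aa` (named 20-vector of frequencies, summing to 1
#'   when any residue was counted) and `codons` (list per amino acid of
#'   named codon frequency vectors; `NULL` without `nt_seqs`).
#' @export
usageProfile <- function(aa_seqs, nt_seqs = NULL) {
  AA <- sort(setdiff(unique(codon2aa()), "*"))
  body <- substring(aa_seqs, 2L)                 # drop initiator Met
  cnt <- table(factor(strsplit(paste(body, collapse = ""), "")[[1L]], levels = AA))
  tot <- sum(cnt)
  aa <- if (tot > 0) as.numeric(cnt) / tot else as.numeric(cnt)
  names(aa) <- AA
  codons <- NULL
  if (!is.null(nt_seqs)) {
    allCod <- unlist(lapply(nt_seqs, function(s) {
      cod <- splitCodons(s)
      cod[-c(1L, length(cod))]                   # exclude start and stop
    }))
    gc <- codon2aa()
    codons <- lapply(AA, function(a) {
      fam <- names(gc)[gc == a]
      n <- table(factor(allCod[allCod %in% fam], levels = fam))
      if (sum(n) > 0) as.numeric(n) / sum(n) else rep(NA_real_, length(fam))
    })
    names(codons) <- AA
    for (a in AA) names(codons[[a]]) <- names(gc)[gc == a]
  }
  list(aa = aa, codons = codons)
}

#' Codon-usage bias as Kullback-Leibler divergence (bits)
#'
#' Per amino acid, KL divergence between the observed codon distribution
#' and the uniform distribution over that amino acid's codons, in bits.
#' Single-codon amino acids give 0; unobserved amino acids give `NA`.
#'
#' @param codon_profile the `codons` element of [usageProfile()].
#' @return named numeric vector of per-amino-acid bits.
#' @export
codonBiasKl <- function(codon_profile) {
  vapply(codon_profile, function(p) {
    if (anyNA(p)) return(NA_real_)
    k <- length(p)
    if (k == 1L) return(0)
    nz <- p > 0
    sum(p[nz] * log2(p[nz] * k))
  }, numeric(1))
}

#' Hierarchical clustering of usage profiles with resampling stability
#'
#' Clusters group-level usage profiles with correlation distance and
#' average linkage, and estimates the stability of the 2-cluster split:
#' in each of `runs` resampling rounds every ORF enters its group's
#' resampled profile with probability `p_keep`, and the round reproduces
#' the full-data split when the resampled 2-cluster partition equals the
#' original (up to label swap).
#'
#' @param group_seqs named list: per group, a character vector of peptide
#'   sequences (optionally with a parallel `nt` attribute; only amino-acid
#'   usage is clustered here).
#' @param runs,p_keep,seed resampling settings.
#' @return list with `hclust` (full-data tree), `split` (named 2-cluster
#'   assignment) and `stability` (fraction of runs reproducing it).
#' @export
usageClustering <- function(group_seqs, runs = 100L, p_keep = 0.5, seed = 1L) {
  if (length(group_seqs) < 3L) stop("need at least 3 groups to cluster")
  prof <- function(seqs) usageProfile(seqs)$aa
  full <- t(vapply(group_seqs, prof, numeric(20L)))
  hc <- stats::hclust(corDist(full), method = "average")
  split <- stats::cutree(hc, k = 2L)
  set.seed(seed)
  same <- logical(runs)
  for (r in seq_len(runs)) {
    sub <- lapply(group_seqs, function(s) {
      keep <- s[stats::runif(length(s)) < p_keep]
      if (length(keep) == 0L) keep <- sample(s, 1L)
      keep
    })
    m <- t(vapply(sub, prof, numeric(20L)))
    sp <- stats::cutree(stats::hclust(corDist(m), method = "average"), k = 2L)
    same[r] <- all(sp == split) || all(sp == 3L - split)
  }
  list(hclust = hc, split = split, stability = mean(same))
}

corDist <- function(m) {
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Scan disordered regions for linear peptide motifs
#'
#' Matches regular-expression motifs (ELM-style) against a peptide and
#' keeps matches whose span has mean disorder strictly greater than
#' `min_disorder`.
#'
#' @param aa_seq one peptide sequence.
#' @param disorder per-residue disorder values (same length as `aa_seq`).
#' @param motifs named character vector of regular expressions.
#' @param min_disorder disorder threshold (strict).
#' @return list with `matches` (data.frame: `motif`, `start`, `end`,
#'   `match`, `mean_disorder`) and `density` (matches per residue).
#' @export
motifScan <- function(aa_seq, disorder, motifs, min_disorder = 0.5) {
  n <- nchar(aa_seq)
  if (length(disorder) != n)
    stop(sprintf("disorder length (%d) != peptide length (%d)",
                 length(disorder), n))
  rows <- list()
  for (k in seq_along(motifs)) {
    m <- gregexpr(motifs[[k]], aa_seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      span <- seq(m[j], m[j] + len[j] - 1L)
      md <- mean(disorder[span])
      if (md > min_disorder)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = names(motifs)[k] %||% as.character(k),
          start = m[j], end = m[j] + len[j] - 1L,
          match = substr(aa_seq, m[j], m[j] + len[j] - 1L),
          mean_disorder = md, stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), start = integer(0), end = integer(0),
               match = character(0), mean_disorder = numeric(0))
  list(matches = matches, density = nrow(matches) / n)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Filter proteome-homology hits to one credible best hit per query
#'
#' Keeps hits with E-value below `max_evalue` (the comparison direction is
#' configurable), percent identity > 50, query coverage > 80 %, subject of
#' the same or larger length, and a subject description not flagged as
#' `PREDICTED`, `hypothetical`, `unknown`, `uncharacterized` or `putative`;
#' returns the best remaining hit per query by percent identity.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `query_coverage` (percent), `e_value`,
#'   `query_length`, `subject_length`, `subject_desc`.
#' @param max_evalue E-value threshold.
#' @param evalue_direction `"below"` (keep `e_value < max_evalue`, the
#'   conventional direction) or `"above"`.
#' @param flag_words descriptions containing any of these words (case
#'   insensitive) are dropped.
#' @return data.frame of best hits, one row per surviving query.
#' @export
filterProteomeHits <- function(hits, max_evalue = 1e-5,
                               evalue_direction = c("below", "above"),
                               flag_words = c("PREDICTED", "hypothetical",
                                              "unknown", "uncharacterized",
                                              "putative")) {
  evalue_direction <- match.arg(evalue_direction)
  keepE <- if (evalue_direction == "below") hits$e_value < max_evalue
           else hits$e_value > max_evalue
  flagged <- Reduce(`|`, lapply(flag_words, function(w)
    grepl(w, hits$subject_desc, ignore.case = TRUE)), rep(FALSE, nrow(hits)))
  h <- hits[keepE & hits$percent_identity > 50 & hits$query_coverage > 80 &
              hits$subject_length >= hits$query_length & !flagged, , drop = FALSE]
  h <- h[order(h$query_id, -h$percent_identity), , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}
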