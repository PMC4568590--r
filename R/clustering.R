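#' Effective percent identity and its dynamic cutoff
#'
#' `pidEff()` computes `PID_eff = percent identity x alignment length /
#' query length`, the effective identity used for short-peptide homology.
#' `dynamicCutoff()` gives the length-dependent acceptance threshold
#' `30 + 70 * exp(-(query length + subject length) / 20)` (amino-acid
#' lengths), demanding more identity between shorter matches.
#'
#' @param percent_identity percent identity of the hit (0-100).
#' @param alignment_length aligned length (aa).
#' @param query_length,subject_length sequence lengths (aa).
#' @return numeric.
#' @export
pidEff <- function(percent_identity, alignment_length, query_length) {
  if (any(query_length == 0)) stop("query length must be positive")
  percent_identity * alignment_length / query_length
}

#' @rdname pidEff
#' @export
dynamicCutoff <- function(query_length, subject_length) {
  30 + 70 * exp(-(query_length + subject_length) / 20)
}

#' Build the cross-species homology cluster graph
#'
#' From all-vs-all peptide hits (blast-style columns), constructs a
#' directed graph with an edge per hit satisfying (i) similar size
#' (relative length deviation at most `max_size_dev`), (ii) E-value below
#' `max_evalue`, and (iii) `PID_eff` above the dynamic cutoff (each
#' directed hit tested with its own query length). Non-reciprocal edges
#' are removed; within-species connected components become paralog
#' clusters; between species, edges are added only for reciprocal best
#' hits between paralog clusters (best = maximal `PID_eff` over member
#' pairs, ties by lower E-value then lexicographic id); singleton clusters
#' are dropped.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `query_length`,
#'   `subject_length`.
#' @param species named character vector: species per peptide id.
#' @param categories optional named character vector: category per id
#'   (used by [collapseIsomorphic()]; `novel` status = category not
#'   `annotated`).
#' @param max_evalue,max_size_dev edge criteria.
#' @return list with `clusters` (list of member-id vectors), `species`,
#'   `categories`, `edges` (data.frame of retained undirected edges) and
#'   `graph` (igraph object).
#' @export
buildClusterGraph <- function(hits, species, categories = NULL,
                              max_evalue = 10, max_size_dev = 0.2) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(h)) {
    dev <- abs(h$query_length - h$subject_length) /
      pmax(h$query_length, h$subject_length)
    pe <- pidEff(h$percent_identity, h$alignment_length, h$query_length)
    cut <- dynamicCutoff(h$query_length, h$subject_length)
    h <- h[dev <= max_size_dev & h$e_value < max_evalue & pe > cut, , drop = FALSE]
    h$pid_eff <- pidEff(h$percent_identity, h$alignment_length, h$query_length)
  } else h$pid_eff <- numeric(0)
  ## reciprocity: keep a->b only if b->a also present
  key <- paste(h$query_id, h$subject_id)
  rkey <- paste(h$subject_id, h$query_id)
  h <- h[key %in% rkey, , drop = FALSE]
  h <- h[order(h$query_id, h$subject_id, h$e_value, -h$pid_eff), , drop = FALSE]
  h <- h[!duplicated(paste(h$query_id, h$subject_id)), , drop = FALSE]

  ids <- sort(unique(names(species)))
  ## paralog clusters: within-species connected components
  within <- h[species[h$query_id] == species[h$subject_id], , drop = FALSE]
  gW <- igraph::graph_from_data_frame(
    within[, c("query_id", "subject_id")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(gW)$membership
  ## cluster-level best scores between paralog clusters of different species
  between <- h[species[h$query_id] != species[h$subject_id], , drop = FALSE]
  clEdges <- NULL
  if (nrow(between)) {
    between$cq <- comp[between$query_id]
    between$cs <- comp[between$subject_id]
    between <- between[order(-between$pid_eff, between$e_value,
                             between$query_id, between$subject_id), , drop = FALSE]
    bestPair <- between[!duplicated(paste(between$cq, between$cs)), , drop = FALSE]
    ## reciprocal best: cluster A's best partner among clusters of species S
    bestPair$sp_s <- species[bestPair$subject_id]
    bestOf <- bestPair[!duplicated(paste(bestPair$cq, bestPair$sp_s)), , drop = FALSE]
    bkey <- paste(bestOf$cq, bestOf$cs)
    rbkey <- paste(bestOf$cs, bestOf$cq)
    rbh <- bestOf[bkey %in% rbkey, , drop = FALSE]
    if (nrow(rbh))
      clEdges <- unique(data.frame(
        from = rbh$query_id, to = rbh$subject_id, stringsAsFactors = FALSE))
  }
  withinEdges <- NULL
  if (nrow(within)) {
    upair <- paste(pmin(within$query_id, within$subject_id),
                   pmax(within$query_id, within$subject_id))
    wu <- within[!duplicated(upair), c("query_id", "subject_id"), drop = FALSE]
    withinEdges <- stats::setNames(wu, c("from", "to"))
  }
  edges <- rbind(withinEdges, clEdges)
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else edges, directed = FALSE, vertices = data.frame(name = ids))
  g <- igraph::simplify(g)
  memb <- igraph::components(g)$membership
  clusters <- split(names(memb), memb)
  clusters <- Filter(function(m) length(m) > 1L, clusters)  # no singletons
  names(clusters) <- sprintf("cluster%03d", seq_along(clusters))
  list(clusters = clusters, species = species, categories = categories,
       edges = igraph::as_data_frame(g, what = "edges"), graph = g)
}

#' Collapse isomorphic clusters and apply the report filter
#'
#' Clusters are considered equivalent when their labelled graphs are
#' isomorphic, treating peptides of the same species and category as
#' interchangeable; equivalent clusters are merged into one representative
#' with a multiplicity count. The report keeps clusters spanning at least
#' `min_species` species with at least one novel (non-`annotated`) member.
#'
#' @param cg result of [buildClusterGraph()] (with `categories` set).
#' @param min_species,require_novel report-filter settings.
#' @return data.frame with one row per representative cluster:
#'   `signature`, `multiplicity`, `n_members`, `n_species`, `has_novel`,
#'   `members` (semicolon-joined ids of the representative), `reported`.
#' @export
collapseIsomorphic <- function(cg, min_species = 2L, require_novel = TRUE) {
  stopifnot(!is.null(cg$categories))
  sig <- vapply(cg$clusters, function(m)
    clusterSignature(cg$graph, m, cg$species, cg$categories), character(1))
  rep1 <- !duplicated(sig)
  mult <- as.integer(table(factor(sig, levels = sig[rep1])))
  reps <- cg$clusters[rep1]
  nsp <- vapply(reps, function(m) length(unique(cg$species[m])), integer(1))
  novel <- vapply(reps, function(m)
    any(!cg$categories[m] %in% "annotated"), logical(1))
  data.frame(
    signature = sig[rep1], multiplicity = mult,
    n_members = lengths(reps), n_species = nsp, has_novel = novel,
    members = vapply(reps, paste, character(1), collapse = ";"),
    reported = nsp >= min_species & (!require_novel | novel),
    stringsAsFactors = FALSE, row.names = NULL)
}

## canonical label-aware signature of one cluster subgraph
clusterSignature <- function(g, members, species, categories) {
  sub <- igraph::induced_subgraph(g, members)
  labels <- paste(species[igraph::V(sub)$name],
                  categories[igraph::V(sub)$name], sep = ":")
  colors <- as.integer(factor(labels, levels = sort(unique(labels))))
  perm <- igraph::canonical_permutation(sub, colors = colors)$labeling
  p <- order(perm)                       # p[i] = original vertex at canon pos i
  canonLabels <- labels[p]
  el <- igraph::as_edgelist(sub, names = FALSE)
  if (nrow(el)) {
    e1 <- perm[el[, 1L]]; e2 <- perm[el[, 2L]]
    es <- sort(paste(pmin(e1, e2), pmax(e1, e2), sep = "-"))
  } else es <- character(0)
  paste(paste(canonLabels, collapse = ","), paste(es, collapse = ","), sep = "|")
}

#' Local peptide alignment (internal toy aligner)
#'
#' Smith-Waterman local alignment with the PAM30 matrix (gap open 9,
#' extend 1) via [Biostrings::pairwiseAlignment()], with an approximate
#' small-database Karlin-Altschul E-value. Intended for building test
#' fixtures; production hit tables come from an external search tool.
#'
#' @param queries,subjects named `AAStringSet`s (or named character
#'   vectors).
#' @param lambda,K Karlin-Altschul parameters of the approximation.
#' @return data.frame in the shape expected by [buildClusterGraph()].
#' @export
alignPeptides <- function(queries, subjects, lambda = 0.32, K = 0.14) {
  q <- Biostrings::AAStringSet(queries)
  s <- Biostrings::AAStringSet(subjects)
  stopifnot(!is.null(names(q)), !is.null(names(s)))
  e <- new.env()
  utils::data(list = "PAM30", package = "Biostrings", envir = e)
  mat <- get("PAM30", envir = e)
  res <- list()
  m <- sum(Biostrings::width(s))
  for (i in seq_along(q)) {
    pa <- Biostrings::pairwiseAlignment(
      rep(q[i], length(s)), s, type = "local", substitutionMatrix = mat,
      gapOpening = 9, gapExtension = 1)
    sc <- Biostrings::score(pa)
    res[[i]] <- data.frame(
      query_id = names(q)[i], subject_id = names(s),
      percent_identity = Biostrings::pid(pa),
      alignment_length = Biostrings::nchar(pa),
      e_value = K * Biostrings::width(q[i]) * m * exp(-lambda * sc),
      query_length = Biostrings::width(q[i]),
      subject_length = Biostrings::width(s),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
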