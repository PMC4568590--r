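#' Extract the four conservation features for every ORF
#'
#' Convenience wrapper running [stitchAndFlag()], [selectionScore()],
#' [frameConservationCount()] and the step-profile distances
#' ([orfStepProfiles()], [stepProfileDistance()]) for an ORF catalog. The
#' mean boundary profiles are built over `positive_ids` (the positive
#' training set); distances of all ORFs are measured against them.
#'
#' @param orfset an [ORFSet].
#' @param txset the host [TranscriptSet].
#' @param blocks alignment blocks from [readMaf()].
#' @param track a [ConservationTrack].
#' @param positive_ids ORF ids defining the mean profiles (defaults to all
#'   ORFs in the `annotated` category, or to all ORFs when categories are
#'   unset).
#' @param score_table optional named vector of precomputed selection scores
#'   (switches the score feature to the table backend).
#' @param p_cod,p_nc surrogate event probabilities (see [selectionScore()]).
#' @return list with `features` (data.frame: `orf_id`, `score`,
#'   `n_frame_species`, `d_start`, `d_stop`), `stitched` (list of
#'   [StitchedAlignment]s) and `mean_profiles`.
#' @export
orfFeatures <- function(orfset, txset, blocks, track, positive_ids = NULL,
                        score_table = NULL,
                        p_cod = c(0.55, 0.30, 0.14, 0.01),
                        p_nc = c(0.40, 0.20, 0.35, 0.05)) {
  ids <- orfIds(orfset)
  if (is.null(positive_ids)) {
    cats <- orfCategories(orfset)
    positive_ids <- if (all(is.na(cats))) ids else ids[cats %in% "annotated"]
    if (length(positive_ids) == 0L) positive_ids <- ids
  }
  stitched <- lapply(ids, function(id) stitchAndFlag(orfset, id, blocks))
  names(stitched) <- ids
  score <- if (is.null(score_table)) {
    vapply(stitched, selectionScore, numeric(1), p_cod = p_cod, p_nc = p_nc)
  } else {
    selectionScore(backend = "table", scores = score_table, orf_id = ids)
  }
  nfs <- vapply(stitched, frameConservationCount, numeric(1))
  prof <- orfStepProfiles(orfset, txset, track)
  meanStart <- buildMeanProfile(prof$start[positive_ids, , drop = FALSE])
  meanStop <- buildMeanProfile(prof$stop[positive_ids, , drop = FALSE])
  dStart <- vapply(ids, function(id)
    stepProfileDistance(prof$start[id, ], meanStart), numeric(1))
  dStop <- vapply(ids, function(id)
    stepProfileDistance(prof$stop[id, ], meanStop), numeric(1))
  list(features = data.frame(orf_id = ids, score = unname(score),
                             n_frame_species = unname(nfs),
                             d_start = unname(dStart), d_stop = unname(dStop),
                             stringsAsFactors = FALSE),
       stitched = stitched,
       mean_profiles = list(start = meanStart, stop = meanStop))
}
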