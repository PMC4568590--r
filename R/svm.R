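#' Assemble SVM training sets
#'
#' Positives are `annotated` ORFs whose peptide is in the curated
#' small-protein list, with at most `max_codons` codons, some alignment
#' coverage and a positive selection score, minus an exclusion list of
#' fast-evolving peptides. Negatives are `ncRNA`-category ORFs with
#' alignment coverage and no overlap with the annotated CDS reference.
#'
#' @param orfset a classified [ORFSet].
#' @param features feature data.frame from [orfFeatures()].
#' @param coverage named vector of the best per-species alignment coverage
#'   per ORF (any value > 0 counts as "some coverage"); typically
#'   `maxCoverage()` of the stitched alignments.
#' @param curated_ids ORF ids (or peptide sequences) of curated small
#'   proteins; `NULL` accepts every annotated ORF.
#' @param exclude_ids ORF ids removed from the positives.
#' @param cds_ref CDS reference `GRanges` for the negative-set overlap test.
#' @param max_codons maximum positive-set length (101 codons = 100 aa).
#' @return list with `positives` and `negatives` (ORF id vectors) and
#'   `excluded`.
#' @export
buildTrainingSets <- function(orfset, features, coverage, curated_ids = NULL,
                              exclude_ids = character(0), cds_ref = NULL,
                              max_codons = 101L) {
  info <- orfset@info
  sc <- stats::setNames(features$score, features$orf_id)
  cov <- coverage[info$orf_id]
  curated <- if (is.null(curated_ids)) rep(TRUE, nrow(info))
             else info$orf_id %in% curated_ids | info$aa_seq %in% curated_ids
  pos <- info$orf_id[info$category %in% "annotated" & curated &
                       info$n_codons <= max_codons &
                       cov > 0 & sc[info$orf_id] > 0]
  excluded <- intersect(pos, exclude_ids)
  pos <- setdiff(pos, exclude_ids)
  neg <- info$orf_id[info$category %in% "ncRNA" & cov > 0]
  if (!is.null(cds_ref) && length(neg)) {
    ov <- vapply(neg, function(id) overlapsRef(orfset@ranges[[id]], cds_ref),
                 logical(1))
    neg <- neg[!ov]
  }
  if (length(pos) == 0L) stop("empty positive training set")
  if (length(neg) == 0L) stop("empty negative training set")
  stopifnot(length(intersect(pos, neg)) == 0L)
  list(positives = pos, negatives = neg, excluded = excluded)
}

#' Best per-ORF alignment coverage
#'
#' @param stitched named list of [StitchedAlignment]s.
#' @return named numeric vector, max species coverage per ORF (0 when no
#'   species aligns).
#' @export
maxCoverage <- function(stitched) {
  vapply(stitched, function(s)
    if (length(s@flags$coverage)) max(s@flags$coverage) else 0, numeric(1))
}

#' Fit the linear SVM on whitened conservation features
#'
#' Features are whitened to zero mean and unit variance on the training
#' data (a constant feature gets scale 1 with a warning), then a linear
#' maximum-margin classifier is fitted (cost parameter `C`, default 1).
#'
#' @param x numeric matrix (rows = training ORFs, columns = features).
#' @param y logical or 0/1 vector (TRUE/1 = positive class).
#' @param C regularisation (cost) parameter.
#' @return a [SorfSVM].
#' @export
fitSvm <- function(x, y, C = 1) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (min(table(y)) < 10L)
    warning("fewer than 10 examples in a class")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, popSd)   # population sd: whitening invariant under duplication
  if (any(scl == 0)) {
    warning("constant feature(s): ", paste(colnames(x)[scl == 0], collapse = ", "),
            "; scale set to 1")
    scl[scl == 0] <- 1
  }
  xw <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  fit <- e1071::svm(xw, factor(y, levels = c(FALSE, TRUE)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## e1071 labels the first factor level +1; flip so positives score high
  if (fit$labels[1L] == 1L) { w <- -w; b <- -b }
  names(w) <- colnames(x)
  new("SorfSVM", center = stats::setNames(ctr, colnames(x)),
      scale = stats::setNames(scl, colnames(x)),
      weights = w, bias = b, threshold = 0)
}

#' Margins and decisions of a fitted SVM
#'
#' @param model a [SorfSVM].
#' @param x feature matrix (raw scale; whitening is applied internally).
#' @return data.frame with `margin` (`w . x_whitened + b`) and `predicted`
#'   (`margin >= threshold`).
#' @export
predictSvm <- function(model, x) {
  x <- as.matrix(x)
  xw <- sweep(sweep(x, 2L, model@center), 2L, model@scale, "/")
  margin <- drop(xw %*% model@weights) + model@bias
  data.frame(margin = margin, predicted = margin >= model@threshold)
}

#' Resampled error estimation of the classifier
#'
#' Repeats `runs` times: each positive and negative example joins the
#' training set independently with probability `p_train`; the model is
#' fitted on the training draw and evaluated on the held-out rest. A run
#' where either held-out class is empty is redrawn.
#'
#' @param x feature matrix with rownames.
#' @param pos_ids,neg_ids ORF ids of the two classes (rownames of `x`).
#' @param runs number of resampling runs.
#' @param p_train training-inclusion probability.
#' @param seed RNG seed (recorded in the result).
#' @param C SVM cost parameter.
#' @return list with per-run `fnr` and `fpr` vectors, their means and sds,
#'   and the seed.
#' @export
crossValidate <- function(x, pos_ids, neg_ids, runs = 100L, p_train = 0.5,
                          seed = 1L, C = 1) {
  x <- as.matrix(x)
  stopifnot(all(c(pos_ids, neg_ids) %in% rownames(x)))
  fnr <- fpr <- numeric(runs)
  set.seed(seed)
  for (r in seq_len(runs)) {
    repeat {
      trainPos <- pos_ids[stats::runif(length(pos_ids)) < p_train]
      trainNeg <- neg_ids[stats::runif(length(neg_ids)) < p_train]
      testPos <- setdiff(pos_ids, trainPos)
      testNeg <- setdiff(neg_ids, trainNeg)
      if (length(testPos) && length(testNeg) &&
          length(trainPos) >= 2L && length(trainNeg) >= 2L) break
      message("redrawing resampling run ", r, " (empty class)")
    }
    ids <- c(trainPos, trainNeg)
    fit <- suppressWarnings(
      fitSvm(x[ids, , drop = FALSE], ids %in% trainPos, C = C))
    predPos <- predictSvm(fit, x[testPos, , drop = FALSE])$predicted
    predNeg <- predictSvm(fit, x[testNeg, , drop = FALSE])$predicted
    fnr[r] <- mean(!predPos)
    fpr[r] <- mean(predNeg)
  }
  list(fnr = fnr, fpr = fpr,
       mean_fnr = mean(fnr), sd_fnr = stats::sd(fnr),
       mean_fpr = mean(fpr), sd_fpr = stats::sd(fpr), seed = seed)
}

#' Minimum-average-error ROC cutoff
#'
#' Scans candidate thresholds (midpoints of sorted unique scores, plus the
#' scores themselves) and returns the threshold minimising the
#' average of false negative and false positive rate, `(FNR + FPR) / 2`,
#' with ties broken towards the smallest threshold. Scores at or above the
#' threshold are called positive.
#'
#' @param pos_scores,neg_scores numeric score vectors.
#' @return the selected threshold.
#' @export
rocMinAvgErrorCutoff <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("empty score vector")
  s <- sort(unique(c(pos_scores, neg_scores)))
  cand <- if (length(s) == 1L) s else sort(unique(c((s[-length(s)] + s[-1L]) / 2, s)))
  err <- vapply(cand, function(th)
    (mean(pos_scores < th) + mean(neg_scores >= th)) / 2, numeric(1))
  cand[which.min(err)]
}
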