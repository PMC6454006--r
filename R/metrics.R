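#' @include AllGenerics.R
NULL

.checkSameDim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("reference and prediction masks must have identical dimensions")
}

#' Pixel-level Dice coefficient (DICE_1)
#'
#' Binarizes both labeled masks (any positive id is foreground) and computes
#' \code{2|A.B| / (|A| + |B|)}. Two empty masks agree perfectly (1.0).
#'
#' @param reference,prediction integer labeled masks of identical dimension.
#' @return score in \code{[0, 1]}.
#' @export
dice1 <- function(reference, prediction) {
  .checkSameDim(reference, prediction)
  a <- reference > 0L
  b <- prediction > 0L
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Overlap table between two labeled masks: one row per (reference id,
# prediction id) pair of co-occurring positive labels, with the pixel count.
.overlapPairs <- function(reference, prediction) {
  sel <- reference > 0L & prediction > 0L
  if (!any(sel)) return(data.frame(q = integer(0), p = integer(0),
                                   n = integer(0)))
  tb <- table(q = reference[sel], p = prediction[sel])
  df <- as.data.frame(tb, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  data.frame(q = as.integer(df$q), p = as.integer(df$p), n = df$Freq)
}

# One direction of the object-level score: each object a in A is matched to
# the object of B with maximal overlap (ties to the smallest id; no overlap
# leaves a unmatched), and D(A->B) = sum 2|a.b*| / sum (|a| + |b*|).
.directedObjectDice <- function(sizesA, sizesB, pairs) {
  num <- 0
  den <- sum(sizesA)
  if (nrow(pairs)) {
    ord <- order(pairs$q, -pairs$n, pairs$p)
    pairs <- pairs[ord, ]
    best <- pairs[!duplicated(pairs$q), ]
    num <- 2 * sum(best$n)
    den <- den + sum(sizesB[as.character(best$p)])
  }
  if (den == 0) return(1)
  num / den
}

#' Object-level Ensemble Dice (DICE_2)
#'
#' A symmetric object-matching variant of the Dice coefficient that penalizes
#' splits (one reference nucleus covered by several predictions) and merges
#' (the reverse), which the pixel Dice ignores. Each object of one labeling
#' is matched to the object of the other with maximal pixel overlap (ties to
#' the smallest id); the directed score is the overlap-weighted Dice sum over
#' matches, and DICE_2 is the mean of the two directions. Both-empty masks
#' score 1.0; exactly one empty scores 0.0.
#'
#' @param reference,prediction integer labeled masks of identical dimension.
#' @return score in \code{[0, 1]}.
#' @export
dice2 <- function(reference, prediction) {
  .checkSameDim(reference, prediction)
  emptyQ <- !any(reference > 0L)
  emptyP <- !any(prediction > 0L)
  if (emptyQ && emptyP) return(1)
  if (emptyQ || emptyP) return(0)
  sizesQ <- table(reference[reference > 0L])
  sizesP <- table(prediction[prediction > 0L])
  pairs <- .overlapPairs(reference, prediction)
  dQP <- .directedObjectDice(sizesQ, sizesP, pairs)
  rev <- data.frame(q = pairs$p, p = pairs$q, n = pairs$n)
  dPQ <- .directedObjectDice(sizesP, sizesQ, rev)
  (dQP + dPQ) / 2
}

#' Tile score: mean of the two Dice coefficients
#'
#' @param d1,d2 DICE_1 and DICE_2 values in \code{[0, 1]}.
#' @return \code{(d1 + d2) / 2}, exactly.
#' @export
tileScore <- function(d1, d2) {
  stopifnotScalarIn01(d1, "dice1")
  stopifnotScalarIn01(d2, "dice2")
  (d1 + d2) / 2
}

#' Dataset score: mean of tile scores
#'
#' @param tileScores numeric vector of per-tile scores.
#' @return their arithmetic mean.
#' @export
datasetScore <- function(tileScores) {
  if (length(tileScores) == 0L) stop("no tile scores")
  if (any(tileScores < 0 | tileScores > 1)) stop("scores must be in [0, 1]")
  mean(tileScores)
}

#' Score a set of segmentations
#'
#' Computes DICE_1, DICE_2 and the tile score for each reference/prediction
#' pair and the dataset means.
#'
#' @param references,predictions lists of labeled masks (parallel, optionally
#'   named by tile id).
#' @return a \code{\link{ScoreReport}}.
#' @export
scoreSegmentation <- function(references, predictions) {
  if (length(references) != length(predictions))
    stop("reference and prediction lists differ in length")
  if (length(references) == 0L) stop("no tiles to score")
  ids <- names(references)
  if (is.null(ids)) ids <- sprintf("tile%03d", seq_along(references))
  d1 <- mapply(dice1, references, predictions)
  d2 <- mapply(dice2, references, predictions)
  pt <- data.frame(tile = ids, dice1 = d1, dice2 = d2,
                   score = (d1 + d2) / 2, row.names = NULL,
                   stringsAsFactors = FALSE)
  new("ScoreReport", perTile = pt, dice1 = mean(d1), dice2 = mean(d2),
      score = datasetScore(pt$score))
}

#' Classification accuracy
#'
#' Number of correctly classified cases divided by the total number of cases.
#'
#' @param truth,predicted equal-length label vectors.
#' @return fraction correct in \code{[0, 1]}.
#' @export
classificationAccuracy <- function(truth, predicted) {
  if (length(truth) == 0L) stop("no cases")
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  mean(as.character(truth) == as.character(predicted))
}
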