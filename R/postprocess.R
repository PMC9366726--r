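# Probability maps become final segmentations here: threshold at 0.5,
# remove small 8-connected fragments (area threshold 1024 px at full
# 512 x 512 scale), and take the pixel-wise union over the best few models
# of a cross-validated ensemble.

#' Binarize a probability map
#'
#' Pixels with value `>= threshold` map to 1 (the boundary convention is
#' `>=`, so exactly 0.5 is foreground under the default threshold).
#'
#' @param map a [ProbabilityMap-class] (or numeric matrix).
#' @param threshold scalar strictly inside (0, 1).
#' @return A [BinaryMask-class].
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  m <- if (is(map, "ProbabilityMap")) map@image else map
  binaryMask((m >= threshold) + 0)
}

#' Remove small fragments from a mask
#'
#' Deletes every 8-connected component with area strictly below `minArea`
#' pixels; components with area `>= minArea` (including exactly `minArea`)
#' are untouched. The default 1024 px is calibrated to 512 x 512 inputs;
#' scale it by `(size/512)^2` for other input sizes.
#'
#' @param mask a [BinaryMask-class].
#' @param minArea minimum component area in px.
#' @return A [BinaryMask-class] with small components removed.
#' @export
clearFragments <- function(mask, minArea = 1024) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@image
  im <- m
  storage.mode(im) <- "integer"
  lab <- cpp_label_components(im)
  if (max(lab) == 0) {
    return(mask)
  }
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minArea)
  binaryMask((matrix(lab %in% keep, nrow(m), ncol(m))) + 0)
}

#' Ensemble specification
#'
#' @param nModels models trained (10 cross-validation folds).
#' @param nSelected models entering the union (the 3 best by validation
#'   performance).
#' @param selectionMetric `"dice"` (mean validation Dice, default) or
#'   `"loss"` (validation loss; lower is better).
#' @return A named list of class `EnsembleSpec`.
#' @export
ensembleSpec <- function(nModels = 10L, nSelected = 3L,
                         selectionMetric = c("dice", "loss")) {
  selectionMetric <- match.arg(selectionMetric)
  if (nSelected > nModels) stop("nSelected must be <= nModels")
  structure(
    list(
      nModels = as.integer(nModels), nSelected = as.integer(nSelected),
      selectionMetric = selectionMetric
    ),
    class = "EnsembleSpec"
  )
}

#' Rank ensemble members by validation score
#'
#' Higher scores are better for `"dice"`, lower for `"loss"`; ties break
#' toward the lower model index.
#'
#' @param valScores numeric vector, one score per model.
#' @param spec an [ensembleSpec()].
#' @return Integer indices of the selected models, best first.
#' @export
selectModels <- function(valScores, spec = ensembleSpec()) {
  if (length(valScores) != spec$nModels) {
    stop("expected ", spec$nModels, " validation scores")
  }
  key <- if (spec$selectionMetric == "loss") valScores else -valScores
  order(key, seq_along(valScores))[seq_len(spec$nSelected)]
}

#' Union the best masks of an ensemble
#'
#' Selects the `nSelected` models with the best validation scores and
#' returns the pixel-wise OR of their masks.
#'
#' @param masks list of [BinaryMask-class], one per model.
#' @param valScores numeric vector of validation scores (same length).
#' @param spec an [ensembleSpec()].
#' @return A [BinaryMask-class] union mask.
#' @export
selectAndUnion <- function(masks, valScores, spec = ensembleSpec()) {
  if (length(masks) != length(valScores)) {
    stop("masks and valScores lengths differ")
  }
  if (length(masks) != spec$nModels) {
    stop("expected ", spec$nModels, " masks")
  }
  sel <- selectModels(valScores, spec)
  u <- masks[[sel[1]]]@image
  for (i in sel[-1]) u <- pmax(u, masks[[i]]@image)
  binaryMask(u)
}
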