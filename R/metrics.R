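# Evaluation metrics: hard-count Dice and IoU on binary masks, and the mean
# squared error used to compare predicted and reference LC/NC values.

maskPair <- function(pred, target) {
  x <- if (is(pred, "BinaryMask")) pred@image else pred
  y <- if (is(target, "BinaryMask")) target@image else target
  if (!identical(dim(x), dim(y))) stop("mask shapes differ")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) stop("masks must be binary")
  list(x = x, y = y)
}

#' Dice coefficient of two binary masks
#'
#' `2|X n Y| / (|X| + |Y|)` with hard pixel counts. Two empty masks score 1
#' (perfect agreement on absence).
#'
#' @param pred,target [BinaryMask-class] objects (or 0/1 matrices) of equal
#'   shape.
#' @return Dice in `[0, 1]`.
#' @export
diceCoefficient <- function(pred, target) {
  p <- maskPair(pred, target)
  sx <- sum(p$x)
  sy <- sum(p$y)
  if (sx + sy == 0) {
    return(1)
  }
  2 * sum(p$x * p$y) / (sx + sy)
}

#' Intersection over union of two binary masks
#'
#' `|X n Y| / |X u Y|`; two empty masks score 1.
#'
#' @inheritParams diceCoefficient
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pred, target) {
  p <- maskPair(pred, target)
  un <- sum(pmax(p$x, p$y))
  if (un == 0) {
    return(1)
  }
  sum(p$x * p$y) / un
}

#' Foreground recall (sensitivity) of a predicted mask
#'
#' Fraction of target foreground recovered; 1 when the target is empty.
#'
#' @inheritParams diceCoefficient
#' @return Recall in `[0, 1]`.
#' @export
foregroundRecall <- function(pred, target) {
  p <- maskPair(pred, target)
  sy <- sum(p$y)
  if (sy == 0) {
    return(1)
  }
  sum(p$x * p$y) / sy
}

#' Mean squared error between two value lists
#'
#' Used to compare predicted LC/NC values against reference morphometry.
#'
#' @param predValues,refValues equal-length nonempty numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(predValues, refValues) {
  if (length(predValues) != length(refValues)) stop("length mismatch")
  if (length(predValues) == 0) stop("empty value lists")
  mean((predValues - refValues)^2)
}

#' Score a set of predicted masks against ground truth
#'
#' @param preds list of predicted [BinaryMask-class] objects.
#' @param truths list of reference masks (same length/order).
#' @param ids optional id labels.
#' @return data.frame with one row per image (`id`, `dice`, `iou`,
#'   `recall`) followed by summary rows (mean, sd, min, max).
#' @export
scoreMasks <- function(preds, truths, ids = seq_along(preds)) {
  stopifnot(length(preds) == length(truths))
  rows <- data.frame(
    id = as.character(ids),
    dice = vapply(seq_along(preds), function(i) {
      diceCoefficient(preds[[i]], truths[[i]])
    }, numeric(1)),
    iou = vapply(seq_along(preds), function(i) iou(preds[[i]], truths[[i]]), numeric(1)),
    recall = vapply(seq_along(preds), function(i) {
      foregroundRecall(preds[[i]], truths[[i]])
    }, numeric(1))
  )
  summ <- data.frame(
    id = c("mean", "sd", "min", "max"),
    dice = c(mean(rows$dice), sd(rows$dice), min(rows$dice), max(rows$dice)),
    iou = c(mean(rows$iou), sd(rows$iou), min(rows$iou), max(rows$iou)),
    recall = c(mean(rows$recall), sd(rows$recall), min(rows$recall), max(rows$recall))
  )
  rbind(rows, summ)
}
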