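#' Extract the pixel data of an image-like object
#'
#' @param x a [VideoStack-class], [PerfusionMap-class], [EnhancedImage-class],
#'   [TwoChannelImage-class], [ProbabilityMap-class] or [BinaryMask-class].
#' @return For `VideoStack` the `(H, W, nFrames)` array; for
#'   `TwoChannelImage` an `(H, W, 2)` array (enhanced, perfusion); otherwise
#'   the underlying matrix.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
setMethod("imageData", "VideoStack", function(x) x@frames)
#' @rdname imageData
setMethod("imageData", "PerfusionMap", function(x) x@image)
#' @rdname imageData
setMethod("imageData", "EnhancedImage", function(x) x@image)
#' @rdname imageData
setMethod("imageData", "ProbabilityMap", function(x) x@image)
#' @rdname imageData
setMethod("imageData", "BinaryMask", function(x) x@image)
#' @rdname imageData
setMethod("imageData", "TwoChannelImage", function(x) {
  a <- array(0, c(dim(x@enhanced), 2))
  a[, , 1] <- x@enhanced
  a[, , 2] <- x@perfusion
  a
})

#' Number of frames in a video stack
#' @param x a [VideoStack-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname nFrames
setMethod("nFrames", "VideoStack", function(x) dim(x@frames)[3])

#' Medial radii of a profile
#' @param x a [MedialProfile-class].
#' @return numeric vector of medial radii (pixels).
#' @export
setGeneric("medialRadii", function(x) standardGeneric("medialRadii"))
#' @rdname medialRadii
setMethod("medialRadii", "MedialProfile", function(x) x@distances)

#' Ground-truth table of a phantom bundle
#' @param x a [PhantomBundle-class].
#' @return data.frame of per-MA truth (diameter, min vessel width, BNR).
#' @export
setGeneric("phantomTruth", function(x) standardGeneric("phantomTruth"))
#' @rdname phantomTruth
setMethod("phantomTruth", "PhantomBundle", function(x) x@truth)

#' Per-component morphometry table
#' @param x a [MorphometryReport-class].
#' @return data.frame with LC, NC, BNR per component.
#' @export
setGeneric("morphometryTable", function(x) standardGeneric("morphometryTable"))
#' @rdname morphometryTable
setMethod("morphometryTable", "MorphometryReport", function(x) x@components)

setMethod("show", "VideoStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VideoStack: %d x %d px, %d frames, intensity [%.3f, %.3f]\n",
    d[1], d[2], d[3], min(object@frames), max(object@frames)
  ))
})

setMethod("show", "PerfusionMap", function(object) {
  cat(sprintf(
    "PerfusionMap: %d x %d px, %s, range [%.4f, %.4f]\n",
    nrow(object@image), ncol(object@image),
    if (object@normalized) "normalized" else "raw temporal sd",
    min(object@image), max(object@image)
  ))
})

setMethod("show", "EnhancedImage", function(object) {
  cat(sprintf(
    "EnhancedImage: %d x %d px, range [%.4f, %.4f]\n",
    nrow(object@image), ncol(object@image), min(object@image), max(object@image)
  ))
})

setMethod("show", "TwoChannelImage", function(object) {
  cat(sprintf(
    "TwoChannelImage: %d x %d px, channels (enhanced, perfusion)\n",
    nrow(object@enhanced), ncol(object@enhanced)
  ))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf(
    "ProbabilityMap: %d x %d px, range (%.4g, %.4g)\n",
    nrow(object@image), ncol(object@image), min(object@image), max(object@image)
  ))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf(
    "BinaryMask: %d x %d px, %d foreground px (%.1f%%)\n",
    nrow(object@image), ncol(object@image), sum(object@image),
    100 * mean(object@image)
  ))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d px, %d frames, %d MA bodies, %d vessels (%d distractors), seed %d\n",
    object@frameSize, object@frameSize, object@nFrames,
    length(object@maBodies), length(object@vessels),
    sum(vapply(object@vessels, function(v) is.na(v$attachedTo), logical(1))),
    object@seed
  ))
})

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle\n  ")
  show(object@video)
  cat("  ")
  show(object@mask)
  cat(sprintf("  truth: %d MA(s)\n", nrow(object@truth)))
})

setMethod("show", "MedialProfile", function(object) {
  cat(sprintf(
    "MedialProfile: %d skeleton points, radii [%.2f, %.2f] px, %d border-flagged\n",
    nrow(object@points), min(object@distances), max(object@distances),
    sum(object@borderFlag)
  ))
})

setMethod("show", "MorphometryReport", function(object) {
  cat(sprintf("MorphometryReport: %d component(s)\n", nrow(object@components)))
  print(object@components)
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf(
    "SplitPlan: %d test ids, %d folds (train %s / val %s)\n",
    length(object@testIds), length(object@folds),
    length(object@folds[[1]]$train), length(object@folds[[1]]$val)
  ))
})
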