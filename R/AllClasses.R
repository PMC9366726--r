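#' VideoStack: an ordered stack of grayscale frames
#'
#' The raw acquisition unit: an AOSLO video as a 3-d array `(rows, cols,
#' frames)` with intensities scaled to `[0, 1]`.
#'
#' @slot frames numeric array `(H, W, nFrames)`, finite, in `[0, 1]`.
#' @export
setClass("VideoStack", representation(frames = "array"), validity = function(object) {
  f <- object@frames
  if (length(dim(f)) != 3) return("frames must be a 3-d array (H, W, nFrames)")
  if (!all(is.finite(f))) return("frames must be finite")
  if (min(f) < 0 || max(f) > 1) return("frame intensities must lie in [0, 1]")
  if (dim(f)[3] < 1) return("at least one frame required")
  TRUE
})

#' Construct a VideoStack
#' @param frames numeric array `(H, W, nFrames)` in `[0, 1]`.
#' @return A [VideoStack-class] object.
#' @export
videoStack <- function(frames) new("VideoStack", frames = frames)

#' PerfusionMap: per-pixel temporal standard deviation image
#'
#' Moving blood flickers across frames, so perfused pixels have high temporal
#' standard deviation and appear bright; static tissue is dark.
#'
#' @slot image numeric matrix, nonnegative.
#' @slot normalized logical; `TRUE` once min-max normalized to `[0, 1]`.
#' @export
setClass("PerfusionMap",
  representation(image = "matrix", normalized = "logical"),
  validity = function(object) {
    if (!all(is.finite(object@image))) return("image must be finite")
    if (min(object@image) < 0) return("perfusion values must be nonnegative")
    if (object@normalized && max(object@image) > 1) {
      return("normalized map must lie in [0, 1]")
    }
    TRUE
  }
)

#' Construct a PerfusionMap
#' @param image nonnegative numeric matrix.
#' @param normalized logical flag.
#' @return A [PerfusionMap-class] object.
#' @export
perfusionMap <- function(image, normalized = FALSE) {
  new("PerfusionMap", image = image, normalized = normalized)
}

#' EnhancedImage: inverted, smoothed frame average
#'
#' @slot image numeric matrix in `[0, 1]`.
#' @export
setClass("EnhancedImage", representation(image = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@image))) return("image must be finite")
    if (min(object@image) < 0 || max(object@image) > 1) {
      return("enhanced image must lie in [0, 1]")
    }
    TRUE
  }
)

#' Construct an EnhancedImage
#' @param image numeric matrix in `[0, 1]`.
#' @return An [EnhancedImage-class] object.
#' @export
enhancedImage <- function(image) new("EnhancedImage", image = image)

#' TwoChannelImage: network input (enhanced, perfusion)
#'
#' Channel order is fixed: channel 1 is the enhanced intensity image,
#' channel 2 the perfusion map, both resampled to a common square size.
#'
#' @slot enhanced numeric matrix (channel 1).
#' @slot perfusion numeric matrix (channel 2), same shape.
#' @export
setClass("TwoChannelImage",
  representation(enhanced = "matrix", perfusion = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@enhanced), dim(object@perfusion))) {
      return("channels must share shape")
    }
    if (!all(is.finite(object@enhanced)) || !all(is.finite(object@perfusion))) {
      return("channels must be finite")
    }
    TRUE
  }
)

#' Construct a TwoChannelImage
#' @param enhanced numeric matrix (channel 1).
#' @param perfusion numeric matrix (channel 2), same shape.
#' @return A [TwoChannelImage-class] object.
#' @export
twoChannelImage <- function(enhanced, perfusion) {
  new("TwoChannelImage", enhanced = enhanced, perfusion = perfusion)
}

#' ProbabilityMap: sigmoid network output in (0, 1)
#'
#' @slot image numeric matrix with values strictly inside `(0, 1)`.
#' @export
setClass("ProbabilityMap", representation(image = "matrix"),
  validity = function(object) {
    if (!all(is.finite(object@image))) return("image must be finite")
    if (min(object@image) <= 0 || max(object@image) >= 1) {
      return("probabilities must lie strictly inside (0, 1)")
    }
    TRUE
  }
)

#' Construct a ProbabilityMap
#' @param image numeric matrix in `(0, 1)`.
#' @return A [ProbabilityMap-class] object.
#' @export
probabilityMap <- function(image) new("ProbabilityMap", image = image)

#' BinaryMask: strictly binary segmentation mask
#'
#' The unit of Dice/IoU scoring and morphometry; 1 marks MA tissue (body or
#' attached vessel), 0 background.
#'
#' @slot image numeric matrix over `{0, 1}`.
#' @export
setClass("BinaryMask", representation(image = "matrix"),
  validity = function(object) {
    if (!all(object@image %in% c(0, 1))) return("mask must be strictly binary")
    TRUE
  }
)

#' Construct a BinaryMask
#' @param image numeric matrix over `{0, 1}`.
#' @return A [BinaryMask-class] object.
#' @export
binaryMask <- function(image) {
  m <- image
  storage.mode(m) <- "double"
  new("BinaryMask", image = m)
}

#' PhantomSpec: parameters of one synthetic AOSLO phantom
#'
#' Describes a stated world: MA bodies of known diameter with attached
#' feeding/draining vessels of known width, plus free-floating distractor
#' vessels, rendered as a flickering video over a noisy static background.
#' Geometry uses 1-based pixel-center coordinates `(row, col)`.
#'
#' @slot frameSize integer pixels per side (square frames).
#' @slot nFrames integer number of frames (>= 2).
#' @slot maBodies list of `list(center = c(row, col), diameter, shape)` with
#'   shape one of `"disk"`, `"ellipse"`, `"fusiform"`.
#' @slot vessels list of `list(path = 2-col matrix of (row, col) waypoints,
#'   width, attachedTo = body index or NA for a distractor)`.
#' @slot flickerAmplitude numeric temporal intensity sd of perfused pixels.
#' @slot backgroundNoiseSigma numeric sd of the static background texture.
#' @slot intensityRange numeric `(background level, structure level)` in `[0, 1]`.
#' @slot seed integer; fixes the whole phantom bit-for-bit.
#' @export
setClass("PhantomSpec",
  representation(
    frameSize = "integer", nFrames = "integer", maBodies = "list",
    vessels = "list", flickerAmplitude = "numeric",
    backgroundNoiseSigma = "numeric", intensityRange = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    if (object@frameSize <= 0) return("frameSize must be positive")
    if (object@nFrames < 2) return("nFrames must be >= 2")
    if (object@flickerAmplitude < 0) return("flickerAmplitude must be >= 0")
    if (object@backgroundNoiseSigma < 0) return("backgroundNoiseSigma must be >= 0")
    if (length(object@intensityRange) != 2 ||
      any(object@intensityRange < 0) || any(object@intensityRange > 1)) {
      return("intensityRange must be two values in [0, 1]")
    }
    for (v in object@vessels) {
      if (v$width < 1) return("vessel width must be >= 1 px")
      if (!is.na(v$attachedTo)) {
        body <- object@maBodies[[v$attachedTo]]
        if (body$diameter <= v$width) {
          return("body diameter must exceed the width of every attached vessel")
        }
      }
    }
    TRUE
  }
)

#' PhantomBundle: phantom video, ground-truth mask and morphometry truth
#'
#' @slot video a [VideoStack-class].
#' @slot mask a [BinaryMask-class] covering MA bodies and attached vessels
#'   only (distractors excluded).
#' @slot truth data.frame with one row per MA: `body`, `diameter`,
#'   `minVesselWidth`, `bnr` (= diameter / minVesselWidth exactly).
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomBundle",
  representation(
    video = "VideoStack", mask = "BinaryMask",
    truth = "data.frame", spec = "PhantomSpec"
  ),
  validity = function(object) {
    if (!identical(dim(object@video@frames)[1:2], dim(object@mask@image))) {
      return("video and mask shapes differ")
    }
    if (nrow(object@truth) > 0 &&
      !isTRUE(all.equal(
        object@truth$bnr,
        object@truth$diameter / object@truth$minVesselWidth
      ))) {
      return("truth BNR must equal diameter / min attached-vessel width")
    }
    TRUE
  }
)

#' MedialProfile: skeleton points and their medial radii
#'
#' The skeleton (medial axis) of a segmented object together with the
#' Euclidean distance from each skeleton point to the nearest background
#' pixel. Points whose medial disk would cross the image frame are flagged
#' as border-contaminated.
#'
#' @slot points integer matrix `(N, 2)` of 1-based `(row, col)` coordinates.
#' @slot distances numeric medial radii, one per point, all > 0.
#' @slot borderFlag logical; `TRUE` where the radius is border-contaminated.
#' @export
setClass("MedialProfile",
  representation(points = "matrix", distances = "numeric", borderFlag = "logical"),
  validity = function(object) {
    n <- nrow(object@points)
    if (n < 1) return("profile needs at least one skeleton point")
    if (length(object@distances) != n || length(object@borderFlag) != n) {
      return("points, distances and borderFlag must align")
    }
    if (any(object@distances <= 0)) return("medial radii must be positive")
    TRUE
  }
)

#' MorphometryReport: LC, NC and BNR per segmented component
#'
#' @slot components data.frame with one row per 8-connected component:
#'   `component`, `area`, `lc`, `nc`, `bnr`, `nSkeleton`, `nBorderFlagged`,
#'   and `lcUm`, `ncUm` when a micron scale was supplied.
#' @slot profiles list of [MedialProfile-class], one per component.
#' @slot umPerPx numeric microns per pixel (`NA` when unscaled).
#' @export
setClass("MorphometryReport",
  representation(components = "data.frame", profiles = "list", umPerPx = "numeric")
)

#' SplitPlan: test reservation plus cross-validation folds
#'
#' One fifth of the ids is reserved as the test set; the remaining pool is
#' split into 10 folds, each fold serving once as validation with the other
#' nine as training.
#'
#' @slot testIds ids reserved for testing.
#' @slot folds list of `list(train, val)` id vectors (union = pool, disjoint).
#' @export
setClass("SplitPlan", representation(testIds = "ANY", folds = "list"))
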