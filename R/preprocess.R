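# Multimodal preprocessing: a raw AOSLO video becomes (i) a perfusion map --
# the per-pixel temporal standard deviation, bright where blood moves --
# passed through a denoise/normalize/CLAHE/gamma enhancement chain, and
# (ii) an enhanced intensity image -- inverted, locally smoothed frame
# average -- and the two are concatenated into the network's two-channel
# input.

#' Compute the perfusion map of a video
#'
#' Per-pixel temporal standard deviation across frames, population
#' convention (denominator `nFrames`); the map is min-max normalized later
#' in the enhancement chain, so only the convention needs fixing.
#'
#' @param video a [VideoStack-class] with at least 2 frames.
#' @return A raw (unnormalized) [PerfusionMap-class].
#' @export
computePerfusionMap <- function(video) {
  stopifnot(is(video, "VideoStack"))
  if (nFrames(video) < 2) {
    stop("perfusion map needs at least 2 frames (temporal sd is undefined)")
  }
  f <- video@frames
  m1 <- rowMeans(f, dims = 2)
  m2 <- rowMeans(f^2, dims = 2)
  perfusionMap(sqrt(pmax(m2 - m1^2, 0)), normalized = FALSE)
}

#' Enhancement parameters for the perfusion channel
#'
#' The denoise--enhance chain applies, in order: fast non-local means,
#' min-max normalization to `[0, 1]`, CLAHE, and gamma correction. The
#' algorithms are fixed; every parameter is overridable here.
#'
#' @param nlmPatch odd patch size for non-local means (px).
#' @param nlmSearch odd search-window size (px).
#' @param nlmH filtering strength as a fraction of the image dynamic range.
#' @param claheTiles CLAHE tile grid (tiles x tiles).
#' @param claheClip CLAHE clip limit as a fraction of the tile histogram.
#' @param claheBins CLAHE histogram bins.
#' @param gamma gamma-correction exponent (applied as `x^gamma`).
#' @return A named list of class `EnhanceParams`.
#' @export
enhanceParams <- function(nlmPatch = 7L, nlmSearch = 21L, nlmH = 0.1,
                          claheTiles = 8L, claheClip = 0.01,
                          claheBins = 256L, gamma = 0.8) {
  stopifnot(isOdd(nlmPatch), isOdd(nlmSearch), nlmH >= 0, claheTiles >= 1,
    claheClip > 0, gamma > 0)
  structure(
    list(
      nlmPatch = as.integer(nlmPatch), nlmSearch = as.integer(nlmSearch),
      nlmH = nlmH, claheTiles = as.integer(claheTiles),
      claheClip = claheClip, claheBins = as.integer(claheBins), gamma = gamma
    ),
    class = "EnhanceParams"
  )
}

#' Min-max normalize a matrix to [0, 1]
#'
#' Constant input maps to all zeros ("no signal") rather than dividing 0/0.
#'
#' @param m numeric matrix.
#' @return Matrix rescaled to `[0, 1]`.
#' @export
minMaxNormalize <- function(m) {
  rng <- range(m)
  if (rng[2] == rng[1]) {
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Denoise and enhance a perfusion map
#'
#' Applies the four-step chain in fixed order: non-local-means denoising,
#' min-max normalization, CLAHE, gamma correction. Output lies in `[0, 1]`.
#'
#' @param map a [PerfusionMap-class].
#' @param params an [enhanceParams()] list.
#' @return A normalized [PerfusionMap-class].
#' @export
enhancePerfusion <- function(map, params = enhanceParams()) {
  stopifnot(is(map, "PerfusionMap"))
  m <- map@image
  stopifnotFinite(m, "perfusion map")
  h <- params$nlmH * diff(range(m))
  m <- cpp_nlm_denoise(m, params$nlmPatch, params$nlmSearch, h)
  m <- minMaxNormalize(m)
  m <- cpp_clahe(m, params$claheTiles, params$claheClip, params$claheBins)
  m <- clamp(m, 0, 1)^params$gamma
  perfusionMap(m, normalized = TRUE)
}

#' Compute the enhanced AOSLO image of a video
#'
#' Average over all frames, invert (`1 - x`), then local mean filtering with
#' a square window and reflective borders. Inversion makes perfused lumina
#' bright on AOSLO's multiply-scattered-light contrast.
#'
#' @param video a [VideoStack-class].
#' @param window odd local-mean window in px (`1` = no smoothing).
#' @return An [EnhancedImage-class].
#' @export
computeEnhancedImage <- function(video, window = 5L) {
  stopifnot(is(video, "VideoStack"))
  if (!isOdd(window) || window < 1) stop("window must be odd and >= 1")
  avg <- rowMeans(video@frames, dims = 2)
  inv <- 1 - avg
  out <- if (window == 1) inv else cpp_box_mean(inv, as.integer(window))
  enhancedImage(clamp(out, 0, 1))
}

#' Concatenate enhanced image and perfusion map into a two-channel input
#'
#' Both channels are resampled bilinearly to `size x size`; channel order is
#' fixed as (enhanced, perfusion).
#'
#' @param enhanced an [EnhancedImage-class].
#' @param perfusion a [PerfusionMap-class] (same source shape).
#' @param size output side length in px (the full-scale network uses 512).
#' @return A [TwoChannelImage-class].
#' @export
makeTwoChannel <- function(enhanced, perfusion, size = 512L) {
  stopifnot(is(enhanced, "EnhancedImage"), is(perfusion, "PerfusionMap"))
  if (!identical(dim(enhanced@image), dim(perfusion@image))) {
    stop("enhanced image and perfusion map shapes differ")
  }
  twoChannelImage(
    cpp_resize(enhanced@image, size, size, FALSE),
    cpp_resize(perfusion@image, size, size, FALSE)
  )
}

#' Resize a binary mask with nearest-neighbour sampling
#'
#' Nearest-neighbour preserves binarity; used to bring ground-truth masks to
#' the network input size.
#'
#' @param mask a [BinaryMask-class].
#' @param size output side length in px.
#' @return A [BinaryMask-class] of size `size x size`.
#' @export
resizeMask <- function(mask, size) {
  stopifnot(is(mask, "BinaryMask"))
  binaryMask(cpp_resize(mask@image, size, size, TRUE))
}

#' Preprocess a video end to end
#'
#' Convenience wrapper: perfusion map, enhancement chain, enhanced image,
#' and the two-channel concatenation at the requested size.
#'
#' @param video a [VideoStack-class].
#' @param size network input side length.
#' @param window local-mean window for the enhanced image.
#' @param params an [enhanceParams()] list for the perfusion chain.
#' @return list with `perfusion`, `enhanced`, `twoChannel`.
#' @export
preprocessVideo <- function(video, size = 512L, window = 5L,
                            params = enhanceParams()) {
  perf <- enhancePerfusion(computePerfusionMap(video), params)
  enh <- computeEnhancedImage(video, window)
  list(
    perfusion = perf, enhanced = enh,
    twoChannel = makeTwoChannel(enh, perf, size)
  )
}
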