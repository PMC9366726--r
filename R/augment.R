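# Flip/rotate/scale augmentation, applied jointly to a two-channel image and
# its mask. Rotation angles are enumerated deterministically (2*pi*k/N for
# k = 0..N-1) -- the only reading consistent with the training-set count
# 63 x 32 = 2016 -- while flips and the scale factor are drawn per rotation
# slot under the config seed.

#' Augmentation configuration
#'
#' @param nRotations number of enumerated rotation angles N (default 32,
#'   angles `2*pi*k/N`).
#' @param flipProb probability of a horizontal and (independently) vertical
#'   flip, drawn once per rotation slot.
#' @param scaleRange uniform range of the random scale factor.
#' @param seed integer seed for the flip/scale draws.
#' @return A named list of class `AugmentConfig`.
#' @export
augmentConfig <- function(nRotations = 32L, flipProb = 0.5,
                          scaleRange = c(0.7, 1.4), seed = 1L) {
  if (nRotations < 1) stop("nRotations must be >= 1")
  stopifnot(flipProb >= 0, flipProb <= 1, scaleRange[1] > 0,
    scaleRange[1] <= scaleRange[2])
  structure(
    list(
      nRotations = as.integer(nRotations), flipProb = flipProb,
      scaleRange = as.numeric(scaleRange), seed = as.integer(seed)
    ),
    class = "AugmentConfig"
  )
}

# inverse affine for the forward map p_out = s * R(theta) * F * p_in about
# the image center: inv = F %*% t(R) / s (F is its own inverse)
augmentInverse <- function(theta, s, hflip, vflip) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Fm <- diag(c(if (vflip) -1 else 1, if (hflip) -1 else 1))
  (Fm %*% t(R)) / s
}

#' Augment one image/mask pair
#'
#' Produces exactly `nRotations` output pairs. For slot `k` (0-based): flips
#' are drawn with `flipProb`, the image is rotated by the deterministic angle
#' `2*pi*k/N` about its center, then scaled by a factor drawn uniformly from
#' `scaleRange`. Image channels are interpolated bilinearly, the mask with
#' nearest-neighbour (so it stays binary); out-of-frame regions are filled
#' with the background value 0 and the canvas keeps the input size.
#'
#' @param image a [TwoChannelImage-class].
#' @param mask the matching [BinaryMask-class].
#' @param config an [augmentConfig()].
#' @return A list of `nRotations` elements `list(image, mask)`.
#' @export
augmentPair <- function(image, mask, config = augmentConfig()) {
  stopifnot(is(image, "TwoChannelImage"), is(mask, "BinaryMask"))
  if (!identical(dim(image@enhanced), dim(mask@image))) {
    stop("image and mask sizes differ")
  }
  N <- config$nRotations
  draws <- withSeed(config$seed, {
    lapply(seq_len(N), function(k) {
      list(
        hflip = runif(1) < config$flipProb,
        vflip = runif(1) < config$flipProb,
        scale = runif(1, config$scaleRange[1], config$scaleRange[2])
      )
    })
  })
  lapply(seq_len(N), function(k) {
    theta <- 2 * pi * (k - 1) / N
    d <- draws[[k]]
    inv <- augmentInverse(theta, d$scale, d$hflip, d$vflip)
    out <- twoChannelImage(
      cpp_affine_warp(image@enhanced, inv, FALSE, 0),
      cpp_affine_warp(image@perfusion, inv, FALSE, 0)
    )
    m <- binaryMask(cpp_affine_warp(mask@image, inv, TRUE, 0))
    list(image = out, mask = m)
  })
}

#' Augment a training set
#'
#' Applies [augmentPair()] to every input pair with slot-independent seeds
#' derived from `config$seed`, yielding `length(pairs) * nRotations` pairs
#' (63 originals with N = 32 give 2016).
#'
#' @param pairs list of `list(image, mask)`.
#' @param config an [augmentConfig()].
#' @return Flat list of augmented `list(image, mask)` pairs.
#' @export
augmentSet <- function(pairs, config = augmentConfig()) {
  out <- vector("list", 0)
  for (i in seq_along(pairs)) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, paste0("augment-", i))
    out <- c(out, augmentPair(pairs[[i]]$image, pairs[[i]]$mask, cfg))
  }
  out
}
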