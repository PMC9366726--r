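# Shared fixture builders: everything is generated in code at test time.

# small disk+vessel phantom, cheap to render
quickSpec <- function(frameSize = 48, bodyDiameter = 14, vesselWidth = 4,
                      nFrames = 10, seed = 1, ...) {
  diskPhantomSpec(
    frameSize = frameSize, bodyDiameter = bodyDiameter,
    vesselWidth = vesselWidth, nFrames = nFrames, seed = seed, ...
  )
}

# two-channel pair straight from a bundle (full preprocessing chain)
bundlePair <- function(bundle, size = dim(bundle@mask@image)[1]) {
  pre <- preprocessVideo(bundle@video, size = size)
  list(image = pre$twoChannel, mask = resizeMask(bundle@mask, size))
}

# cheap synthetic two-channel image from raw matrices (skips enhancement)
rawPair <- function(mask, noise = 0.02, seed = 1) {
  m <- if (is(mask, "BinaryMask")) mask@image else mask
  withSeed(seed, {
    ch1 <- clamp(0.3 + 0.4 * m + matrix(rnorm(length(m), 0, noise), nrow(m)), 0, 1)
    ch2 <- clamp(0.1 + 0.7 * m + matrix(rnorm(length(m), 0, noise), nrow(m)), 0, 1)
    list(image = twoChannelImage(ch1, ch2), mask = binaryMask(m))
  })
}

# brute-force flood fill labelling (4 loops, queue), independent of the
# compiled component labeller
floodFillLabels <- function(m) {
  H <- nrow(m)
  W <- ncol(m)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c0 in seq_len(W)) {
    for (r0 in seq_len(H)) {
      if (m[r0, c0] == 1 && lab[r0, c0] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(r0, c0))
        lab[r0, c0] <- nxt
        while (length(queue) > 0) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (dr in -1:1) {
            for (dc in -1:1) {
              r <- p[1] + dr
              c <- p[2] + dc
              if (r >= 1 && r <= H && c >= 1 && c <= W &&
                m[r, c] == 1 && lab[r, c] == 0L) {
                lab[r, c] <- nxt
                queue[[length(queue) + 1]] <- c(r, c)
              }
            }
          }
        }
      }
    }
  }
  lab
}

# exhaustive nearest-background-pixel distance, the EDT oracle
bruteEDT <- function(m) {
  H <- nrow(m)
  W <- ncol(m)
  bg <- which(m == 0, arr.ind = TRUE)
  out <- matrix(0, H, W)
  fg <- which(m == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out
}
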