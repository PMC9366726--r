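test_that("perfusion map equals the per-pixel temporal sd oracle", {
  v <- withSeed(4, videoStack(array(runif(16 * 16 * 7), c(16, 16, 7))))
  got <- computePerfusionMap(v)@image
  oracle <- matrix(0, 16, 16)
  for (r in 1:16) {
    for (c in 1:16) {
      x <- v@frames[r, c, ]
      oracle[r, c] <- sqrt(mean((x - mean(x))^2)) # population convention
    }
  }
  expect_lt(max(abs(got - oracle)), 1e-9)
})

test_that("perfusion map closed forms and error cases", {
  const <- videoStack(array(0.4, c(8, 8, 5)))
  expect_equal(computePerfusionMap(const)@image, matrix(0, 8, 8))
  twoFrames <- array(0, c(4, 4, 2))
  twoFrames[2, 3, 2] <- 1 # pixel alternating 0/1: population sd = 1/2
  got <- computePerfusionMap(videoStack(twoFrames))@image
  expect_equal(got[2, 3], 0.5)
  expect_equal(got[1, 1], 0)
  expect_error(computePerfusionMap(videoStack(array(0.1, c(4, 4, 1)))), "2 frames")
})

test_that("perfusion map separates flickering vessels from static background", {
  b <- generatePhantom(quickSpec(frameSize = 48, nFrames = 20, seed = 2))
  pm <- computePerfusionMap(b@video)@image
  m <- b@mask@image
  expect_gt(mean(pm[m == 1]), 5 * mean(pm[m == 0]))
})

test_that("min-max normalization and gamma behave as stated", {
  expect_equal(
    minMaxNormalize(matrix(c(10, 35, 60), 1, 3)),
    matrix(c(0, 0.5, 1), 1, 3)
  )
  expect_equal(minMaxNormalize(matrix(7, 3, 3)), matrix(0, 3, 3))
  # rank order is preserved by normalization
  x <- matrix(withSeed(1, runif(50, 2, 9)), 5, 10)
  expect_identical(order(minMaxNormalize(x)), order(x))
  # gamma = 1 leaves the normalized map unchanged
  m <- perfusionMap(matrix(withSeed(2, runif(64)), 8, 8))
  p1 <- enhanceParams(gamma = 1)
  p8 <- enhanceParams(gamma = 0.8)
  e1 <- enhancePerfusion(m, p1)@image
  e8 <- enhancePerfusion(m, p8)@image
  expect_equal(e8, e1^0.8, tolerance = 1e-12)
})

test_that("enhancement chain maps constants to constants and stays in [0,1]", {
  const <- perfusionMap(matrix(0.3, 16, 16))
  out <- enhancePerfusion(const)@image
  expect_equal(max(out) - min(out), 0)
  b <- generatePhantom(quickSpec(frameSize = 48, nFrames = 12, seed = 5))
  enh <- enhancePerfusion(computePerfusionMap(b@video))@image
  expect_gte(min(enh), 0)
  expect_lte(max(enh), 1)
  expect_error(
    enhancePerfusion(perfusionMap(matrix(c(1, NA, 1, 1), 2, 2))),
    "finite|missing"
  )
})

test_that("non-local means denoising reduces background noise, keeps edges", {
  m <- matrix(0.2, 48, 48)
  m[20:30, 20:30] <- 0.8
  noisy <- m + matrix(withSeed(3, rnorm(48 * 48, 0, 0.05)), 48, 48)
  den <- MAseg:::cpp_nlm_denoise(noisy, 7L, 21L, 0.1 * diff(range(noisy)))
  # residual sd on the flat background drops
  expect_lt(sd(den[1:15, 1:15] - 0.2), sd(noisy[1:15, 1:15] - 0.2))
  # the bright plateau survives
  expect_gt(mean(den[22:28, 22:28]), 0.6)
})

test_that("enhanced image is the smoothed inverted frame average", {
  const <- videoStack(array(0.3, c(8, 8, 4)))
  expect_equal(computeEnhancedImage(const, 5)@image, matrix(0.7, 8, 8))
  # window = 1: exact inversion of the average
  v <- withSeed(6, videoStack(array(runif(8 * 8 * 3, 0, 1), c(8, 8, 3))))
  expect_equal(
    computeEnhancedImage(v, 1)@image,
    1 - rowMeans(v@frames, dims = 2)
  )
  # checkerboard: interior local means after inversion are 4/9 or 5/9
  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  vcb <- videoStack(array(rep(cb, 2), c(8, 8, 2)))
  enh <- computeEnhancedImage(vcb, 3)@image
  inner <- enh[3:6, 3:6]
  expect_true(all(abs(inner - 4 / 9) < 1e-12 | abs(inner - 5 / 9) < 1e-12))
  # window sums against a brute-force oracle (reflective border)
  oracle <- matrix(0, 8, 8)
  inv <- 1 - cb
  refl <- function(i) ifelse(i < 1, 1 - i, ifelse(i > 8, 16 - i + 1, i))
  for (r in 1:8) {
    for (c in 1:8) {
      s <- 0
      for (dr in -1:1) for (dc in -1:1) s <- s + inv[refl(r + dr), refl(c + dc)]
      oracle[r, c] <- s / 9
    }
  }
  expect_equal(enh, oracle, tolerance = 1e-12)
  expect_error(computeEnhancedImage(v, 4), "odd")
})

test_that("two-channel concatenation fixes order, size and identity resample", {
  e <- enhancedImage(matrix(withSeed(7, runif(64)), 8, 8))
  p <- perfusionMap(matrix(withSeed(8, runif(64)), 8, 8))
  tc <- makeTwoChannel(e, p, size = 8)
  expect_equal(tc@enhanced, e@image) # identity resample, channel 0
  expect_equal(tc@perfusion, p@image)
  up <- makeTwoChannel(e, p, size = 16)
  expect_equal(dim(up@enhanced), c(16L, 16L))
  constE <- enhancedImage(matrix(0.25, 8, 8))
  constP <- perfusionMap(matrix(0.5, 8, 8))
  cc <- makeTwoChannel(constE, constP, size = 12)
  expect_equal(cc@enhanced, matrix(0.25, 12, 12))
  expect_equal(cc@perfusion, matrix(0.5, 12, 12))
  expect_error(
    makeTwoChannel(enhancedImage(matrix(0.1, 4, 4)), p, 8),
    "shapes differ"
  )
})

test_that("end-to-end, both channels are brighter on the MA than background", {
  b <- generatePhantom(quickSpec(frameSize = 64, bodyDiameter = 16, nFrames = 20, seed = 10))
  pre <- preprocessVideo(b@video, size = 64)
  m <- b@mask@image
  expect_gt(mean(pre$twoChannel@enhanced[m == 1]), mean(pre$twoChannel@enhanced[m == 0]))
  expect_gt(mean(pre$twoChannel@perfusion[m == 1]), mean(pre$twoChannel@perfusion[m == 0]))
})

test_that("mask resizing preserves binarity", {
  b <- generatePhantom(quickSpec(frameSize = 48, nFrames = 3))
  rs <- resizeMask(b@mask, 64)
  expect_true(all(rs@image %in% c(0, 1)))
  expect_equal(dim(rs@image), c(64L, 64L))
})
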