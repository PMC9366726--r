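test_that("medial radii match the exhaustive nearest-background oracle", {
  shapes <- list()
  m1 <- matrix(0, 40, 40)
  m1[10:14, 5:35] <- 1 # bar
  shapes$bar <- m1
  m2 <- matrix(0, 40, 40)
  for (r in 1:40) for (c in 1:40) if ((r - 20)^2 + (c - 20)^2 < 100) m2[r, c] <- 1
  shapes$disk <- m2
  m3 <- matrix(withSeed(12, rbinom(1600, 1, 0.45)), 40, 40)
  shapes$random <- m3
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    edt <- sqrt(MAseg:::cpp_edt_sq(matrix(as.integer(m), 40, 40)))
    oracle <- bruteEDT(m)
    fg <- m == 1
    expect_equal(edt[fg], oracle[fg], tolerance = 1e-12, label = nm)
  }
})

test_that("bar and disk profiles recover the constructed calibers", {
  # 5 px wide, 60 px long bar: interior medial radii are 2.5 +- 0.5
  m <- matrix(0, 70, 70)
  m[33:37, 5:64] <- 1
  prof <- medialProfile(binaryMask(m))
  interior <- prof@distances[prof@points[, 2] > 10 & prof@points[, 2] < 59]
  expect_true(all(abs(interior - 2.5) <= 0.5))
  # filled disk of radius 10: max radius within +-1 of 10
  d <- matrix(0, 48, 48)
  for (r in 1:48) for (c in 1:48) if ((r - 24)^2 + (c - 24)^2 < 100) d[r, c] <- 1
  profD <- medialProfile(binaryMask(d))
  expect_lt(abs(max(profD@distances) - 10), 1)
  # single isolated pixel: N = 1, d = 1
  s <- matrix(0, 9, 9)
  s[5, 5] <- 1
  profS <- medialProfile(binaryMask(s))
  expect_equal(nrow(profS@points), 1)
  expect_equal(profS@distances, 1)
  expect_error(medialProfile(binaryMask(matrix(0, 5, 5))), "empty")
})

test_that("LC, NC and BNR formulas follow the sorted distance list", {
  prof <- new("MedialProfile",
    points = cbind(5:7, 5:7), distances = c(1, 2, 5),
    borderFlag = rep(FALSE, 3)
  )
  expect_equal(largestCaliber(prof), 10) # 2 * max
  tenOnes <- new("MedialProfile",
    points = cbind(rep(5, 12), 1:12),
    distances = c(rep(1, 10), 9, 9), borderFlag = rep(FALSE, 12)
  )
  expect_equal(narrowestCaliber(tenOnes), 2) # ten smallest all 1
  short <- new("MedialProfile",
    points = cbind(rep(5, 4), 1:4),
    distances = rep(2, 4), borderFlag = rep(FALSE, 4)
  )
  expect_equal(narrowestCaliber(short), 4) # fewer than 10: use all
  expect_equal(bodyToNeckRatio(20, 5), 4)
  expect_equal(bodyToNeckRatio(3, 3), 1)
  expect_error(bodyToNeckRatio(10, 0), "positive")
})

test_that("disk-with-vessel phantom recovers LC, NC and BNR end to end", {
  b <- generatePhantom(diskPhantomSpec(
    frameSize = 96, bodyDiameter = 20,
    vesselWidth = 5, nFrames = 3
  ))
  prof <- medialProfile(b@mask)
  lc <- largestCaliber(prof)
  nc <- narrowestCaliber(prof)
  expect_lt(abs(lc - 20), 2.1) # body diameter within rasterization tolerance
  expect_lte(abs(nc - 5), 1) # vessel width within +-1 px
  bnr <- bodyToNeckRatio(lc, nc)
  expect_lt(abs(bnr - 4) / 4, 0.25)
})

test_that("morphometry reports per 8-connected component", {
  m <- matrix(0, 60, 120)
  for (r in 1:60) for (c in 1:60) if ((r - 30)^2 + (c - 30)^2 < 64) m[r, c] <- 1
  m[30, 1:30] <- 1
  m[29, 1:30] <- 1
  m[31, 1:30] <- 1 # 3 px vessel into the disk
  m[10:12, 90:115] <- 1 # separate bar component
  rep <- morphometry(binaryMask(m))
  tab <- morphometryTable(rep)
  expect_equal(nrow(tab), 2)
  main <- tab[which.max(tab$area), ]
  expect_lt(abs(main$lc - 16) / 16, 0.15)
  expect_equal(main$bnr, main$lc / main$nc)
  # micron conversion is pass-through metadata
  repUm <- morphometry(binaryMask(m), umPerPx = 2.5)
  expect_equal(morphometryTable(repUm)$lcUm, morphometryTable(repUm)$lc * 2.5)
})

test_that("calibers are scale-covariant and rotation-robust", {
  b <- generatePhantom(diskPhantomSpec(
    frameSize = 64, bodyDiameter = 16,
    vesselWidth = 6, nFrames = 3, distractor = FALSE
  ))
  m <- b@mask@image
  prof1 <- medialProfile(b@mask)
  lc1 <- largestCaliber(prof1)
  nc1 <- narrowestCaliber(prof1)
  # integer 2x upscale (pixel replication)
  up <- m[rep(seq_len(64), each = 2), rep(seq_len(64), each = 2)]
  prof2 <- medialProfile(binaryMask(up))
  expect_lt(abs(largestCaliber(prof2) - 2 * lc1) / (2 * lc1), 0.10)
  expect_lt(abs(narrowestCaliber(prof2) - 2 * nc1) / (2 * nc1), 0.10)
  bnr1 <- lc1 / nc1
  bnr2 <- largestCaliber(prof2) / narrowestCaliber(prof2)
  expect_lt(abs(bnr2 - bnr1) / bnr1, 0.15)
  # 45 degree rotation changes calibers by < 10%; a wider phantom keeps the
  # diagonal rasterization error (~0.5 px absolute on NC) inside the band
  bw <- generatePhantom(diskPhantomSpec(
    frameSize = 120, bodyDiameter = 24,
    vesselWidth = 12, nFrames = 3, distractor = FALSE
  ))
  inv <- MAseg:::augmentInverse(pi / 4, 1, FALSE, FALSE)
  rot <- binaryMask(MAseg:::cpp_affine_warp(bw@mask@image, inv, TRUE, 0))
  profR <- medialProfile(rot)
  prof0 <- medialProfile(bw@mask)
  expect_lt(
    abs(largestCaliber(profR) - largestCaliber(prof0)) / largestCaliber(prof0),
    0.10
  )
  expect_lt(
    abs(narrowestCaliber(profR) - narrowestCaliber(prof0)) / narrowestCaliber(prof0),
    0.10
  )
})

test_that("border-contaminated skeleton points are flagged", {
  m <- matrix(0, 40, 40)
  m[1:12, 1:12] <- 1 # blob clipped by the frame corner
  prof <- medialProfile(binaryMask(m))
  expect_gt(sum(prof@borderFlag), 0)
  # interior object: nothing flagged
  m2 <- matrix(0, 40, 40)
  m2[15:25, 15:25] <- 1
  expect_equal(sum(medialProfile(binaryMask(m2))@borderFlag), 0)
})
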