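test_that("phantom generation is seeded and bit-reproducible", {
  sp <- quickSpec(seed = 42)
  b1 <- generatePhantom(sp)
  b2 <- generatePhantom(sp)
  expect_identical(b1@video@frames, b2@video@frames)
  expect_identical(b1@mask@image, b2@mask@image)
  expect_identical(b1@truth, b2@truth)
})

test_that("zero flicker and zero noise give identical frames", {
  sp <- quickSpec(flickerAmplitude = 0, backgroundNoiseSigma = 0, nFrames = 5)
  b <- generatePhantom(sp)
  f <- b@video@frames
  for (k in 2:5) expect_identical(f[, , k], f[, , 1])
})

test_that("truth BNR is diameter over min attached width by construction", {
  b <- generatePhantom(quickSpec(bodyDiameter = 20, vesselWidth = 5, frameSize = 64))
  expect_equal(phantomTruth(b)$bnr, 4.0)
  expect_equal(phantomTruth(b)$diameter, 20)
  expect_equal(phantomTruth(b)$minVesselWidth, 5)
})

test_that("mask is strictly binary, covers bodies+attached vessels, excludes distractors", {
  sp <- quickSpec(frameSize = 64, bodyDiameter = 16, vesselWidth = 4, distractor = TRUE)
  b <- generatePhantom(sp)
  m <- b@mask@image
  expect_true(all(m %in% c(0, 1)))
  # the distractor column (20% of the frame width) flickers but is unmasked
  # away from where the attached horizontal vessels cross it
  n <- sp@frameSize
  distCol <- MAseg:::parityCoord(n * 0.2, 4)
  expect_equal(sum(m[1:15, floor(distCol) + (0:1)]), 0)
  # flicker distinguishes distractor pixels from static background
  sds <- apply(b@video@frames, c(1, 2), sd)
  expect_gt(mean(sds[, floor(distCol)]), 5 * mean(sds[, n - 2]))
})

test_that("perfused pixels flicker at the requested amplitude", {
  # sample sd of n=60 Gaussian draws has ~9% relative spread, so the 20%
  # band is checked in distribution: the bulk of perfused pixels inside it,
  # and their mean much closer
  sp <- quickSpec(frameSize = 48, nFrames = 60, seed = 9)
  b <- generatePhantom(sp)
  sds <- apply(b@video@frames, c(1, 2), sd)
  perf <- sds[b@mask@image == 1]
  amp <- sp@flickerAmplitude
  expect_gt(mean(abs(perf - amp) / amp <= 0.2), 0.9)
  expect_lt(abs(mean(perf) - amp) / amp, 0.05)
  # background pixels are static (frozen texture)
  bgSd <- apply(b@video@frames[1:5, 1:5, ], c(1, 2), sd)
  expect_equal(max(bgSd), 0)
})

test_that("ill-posed specs are rejected", {
  twoBodies <- phantomSpec(
    frameSize = 64,
    maBodies = list(
      list(center = c(30, 30), diameter = 16, shape = "disk"),
      list(center = c(34, 34), diameter = 16, shape = "disk")
    ),
    vessels = list(
      list(path = rbind(c(30, 1), c(30, 30)), width = 4, attachedTo = 1L),
      list(path = rbind(c(34, 34), c(34, 64)), width = 4, attachedTo = 2L)
    )
  )
  expect_error(generatePhantom(twoBodies), "overlapping")
  expect_error(
    phantomSpec(
      frameSize = 64,
      maBodies = list(list(center = c(30, 30), diameter = 16, shape = "disk")),
      vessels = list(list(path = rbind(c(30, 1), c(30, 30)), width = 0.5, attachedTo = 1L))
    ),
    "width"
  )
  expect_error(
    phantomSpec(
      frameSize = 64,
      maBodies = list(list(center = c(30, 30), diameter = 6, shape = "disk")),
      vessels = list(list(path = rbind(c(30, 1), c(30, 30)), width = 8, attachedTo = 1L))
    ),
    "diameter"
  )
})

test_that("fixture sets have the requested size, diversity and determinism", {
  rg <- list(frameSize = 48, nFrames = 4)
  s1 <- makeFixtureSet(5, seed = 3, specRanges = rg)
  s2 <- makeFixtureSet(5, seed = 3, specRanges = rg)
  expect_length(s1, 5)
  expect_identical(
    lapply(s1, function(b) b@video@frames),
    lapply(s2, function(b) b@video@frames)
  )
  one <- makeFixtureSet(1, seed = 8, specRanges = rg)
  expect_length(one, 1)
  expect_true(validObject(one[[1]]))
  expect_true(all(phantomTruth(one[[1]])$minVesselWidth >= 1))
  expect_error(makeFixtureSet(3, seed = 1, specRanges = list(shapes = character(0))), "empty")
  expect_error(makeFixtureSet(0, seed = 1), "nImages")
})

test_that("all body shapes rasterize with the stated caliber", {
  for (shape in c("disk", "ellipse", "fusiform")) {
    sp <- phantomSpec(
      frameSize = 72, nFrames = 3,
      maBodies = list(list(center = c(36.5, 36.5), diameter = 20, shape = shape)),
      vessels = list(list(path = rbind(c(36, 1), c(36, 36)), width = 5, attachedTo = 1L))
    )
    b <- generatePhantom(sp)
    prof <- medialProfile(b@mask)
    expect_lt(abs(largestCaliber(prof) - 20), 2.1, label = shape)
  }
})
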