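test_that("composite loss matches a scalar-loop oracle on random 8x8 pairs", {
  cfg <- lossConfig(alpha = 0.2, clipEps = 1e-7)
  for (seed in 1:5) {
    pred <- matrix(withSeed(seed, runif(64, 0.01, 0.99)), 8, 8)
    target <- matrix(withSeed(seed + 100, rbinom(64, 1, 0.5)), 8, 8)
    # independent elementwise-loop oracle
    bce <- 0
    sx <- 0
    sy <- 0
    sxy <- 0
    for (i in 1:8) {
      for (j in 1:8) {
        x <- min(max(pred[i, j], cfg$clipEps), 1 - cfg$clipEps)
        y <- target[i, j]
        bce <- bce - (y * log(x) + (1 - y) * log(1 - x))
        sx <- sx + x
        sy <- sy + y
        sxy <- sxy + x * y
      }
    }
    oracle <- bce / 64 + cfg$alpha * (1 - (2 * sxy + 1) / (sx + sy + 1))
    expect_equal(compositeLoss(pred, target, cfg), oracle, tolerance = 1e-6)
  }
})

test_that("composite loss closed forms: perfect prediction and 0.5 everywhere", {
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  eps <- 1e-7
  cfg <- lossConfig(alpha = 0.2, clipEps = eps)
  perfect <- clamp(y, eps, 1 - eps)
  expect_lt(compositeLoss(perfect, y, cfg), 1e-5)
  # with a smaller clip the perfect-prediction loss shrinks further
  cfg2 <- lossConfig(alpha = 0.2, clipEps = 1e-9)
  expect_lt(
    compositeLoss(clamp(y, 1e-9, 1 - 1e-9), y, cfg2),
    compositeLoss(perfect, y, cfg)
  )
  # flat 0.5: the BCE term is exactly log(2) per pixel
  half <- matrix(0.5, 8, 8)
  lg <- MAseg:::lossAndGrad(half, y, cfg)
  expect_equal(lg$bce, log(2))
  expect_error(compositeLoss(matrix(0.5, 4, 4), y), "shape")
})

test_that("the Dice term is invariant under simultaneous flips", {
  pred <- matrix(withSeed(3, runif(64, 0.05, 0.95)), 8, 8)
  y <- matrix(withSeed(4, rbinom(64, 1, 0.5)), 8, 8)
  d1 <- MAseg:::lossAndGrad(pred, y, lossConfig())$dice
  flip <- function(m) m[nrow(m):1, ncol(m):1]
  d2 <- MAseg:::lossAndGrad(flip(pred), flip(y), lossConfig())$dice
  expect_equal(d1, d2)
})

test_that("backpropagation matches finite differences", {
  net <- buildNetwork(networkConfig("tiny"), seed = 11)
  x <- array(withSeed(5, runif(32 * 32 * 2)), c(32, 32, 2))
  y <- matrix(withSeed(6, rbinom(32 * 32, 1, 0.3)), 32, 32)
  cfg <- lossConfig()
  fw <- MAseg:::netForward(net, x, cache = TRUE)
  lg <- MAseg:::lossAndGrad(fw$prob, y, cfg)
  gr <- MAseg:::netBackward(net, fw, lg$grad)
  numGrad <- function(nm, i) {
    eps <- 1e-6
    n2 <- net
    n2@params[[nm]]$w[i] <- n2@params[[nm]]$w[i] + eps
    l1 <- MAseg:::lossAndGrad(MAseg:::netForward(n2, x)$prob, y, cfg)$loss
    n2@params[[nm]]$w[i] <- n2@params[[nm]]$w[i] - 2 * eps
    l0 <- MAseg:::lossAndGrad(MAseg:::netForward(n2, x)$prob, y, cfg)$loss
    (l1 - l0) / (2 * eps)
  }
  idx <- withSeed(7, lapply(c("enc1a", "enc5b", "dec1a", "dec5b", "head"), function(nm) {
    list(nm = nm, i = sample(length(net@params[[nm]]$w), 1))
  }))
  for (p in idx) {
    expect_equal(gr[[p$nm]]$gw[p$i], numGrad(p$nm, p$i),
      tolerance = 1e-4, label = p$nm
    )
  }
})

test_that("network shape/range contract and seeded initialization", {
  net <- buildNetwork(networkConfig("tiny"), seed = 3)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  pm <- predictMap(net, x)
  expect_equal(dim(pm@image), c(64L, 64L))
  expect_gt(min(pm@image), 0)
  expect_lt(max(pm@image), 1)
  # decoder has 5 blocks (two convs each)
  decNames <- grep("^dec", names(net@params), value = TRUE)
  expect_length(decNames, 10)
  net2 <- buildNetwork(networkConfig("tiny"), seed = 3)
  expect_identical(net@params, net2@params)
  net3 <- buildNetwork(networkConfig("tiny"), seed = 4)
  expect_false(identical(net@params, net3@params))
  # inference is deterministic
  expect_identical(predictMap(net, x)@image, pm@image)
  expect_error(predictMap(net, array(0.1, c(30, 30, 2))), "divisible")
  expect_error(
    buildNetwork(networkConfig("tiny", decoderChannels = c(8L, 8L))),
    "decoderChannels"
  )
  expect_error(networkConfig(pretrained = TRUE), "offline")
})

test_that("the full-scale preset keeps the stated decoder widths and saves checkpoints", {
  cfg <- networkConfig("large")
  expect_equal(cfg$decoderChannels, c(256L, 128L, 64L, 32L, 16L))
  expect_message(networkConfig("efficientnet-b3"), "offline")
  net <- buildNetwork(networkConfig("tiny"), seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(net, path, history = data.frame(epoch = 1, trainLoss = 0.5))
  back <- loadCheckpoint(path)
  expect_identical(back@params, net@params)
  sidecar <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"))
  expect_equal(sidecar$config$encoder, "tiny")
  expect_equal(sidecar$history[[1]]$trainLoss, 0.5)
})

test_that("split arithmetic reproduces the 63:7:17 scheme", {
  plan <- makeSplit(seq_len(87), seed = 1)
  expect_length(plan@testIds, 17)
  pool <- setdiff(seq_len(87), plan@testIds)
  expect_length(pool, 70)
  for (f in plan@folds) {
    expect_length(f$val, 7)
    expect_length(f$train, 63)
    expect_setequal(c(f$train, f$val), pool)
    expect_length(intersect(f$train, f$val), 0)
  }
  plan50 <- makeSplit(seq_len(50), seed = 2)
  expect_length(plan50@testIds, 10)
  expect_length(plan50@folds[[1]]$val, 4)
  expect_length(plan50@folds[[1]]$train, 36)
  expect_error(makeSplit(seq_len(10)), "15")
})

test_that("split invariants hold across seeds and are seed-deterministic", {
  for (seed in c(3, 17, 91)) {
    ids <- paste0("ma", 1:23)
    plan <- makeSplit(ids, seed = seed)
    pool <- setdiff(ids, plan@testIds)
    expect_length(plan@testIds, 4)
    sizes <- vapply(plan@folds, function(f) length(f$val), numeric(1))
    expect_equal(sum(sizes), length(pool))
    expect_lte(max(sizes) - min(sizes), 1)
    for (f in plan@folds) expect_setequal(c(f$train, f$val), pool)
  }
  expect_identical(makeSplit(1:20, seed = 5), makeSplit(1:20, seed = 5))
})

test_that("plateau scheduler drops the learning rate by 10x after 5 stalls", {
  st <- list(best = Inf, since = 0L, lr = 0.001, improved = FALSE)
  st <- MAseg:::plateauStep(st, 0.5, 5L, 0.1) # improvement
  expect_equal(st$lr, 0.001)
  for (k in 1:4) st <- MAseg:::plateauStep(st, 0.5, 5L, 0.1)
  expect_equal(st$lr, 0.001) # four stalls: not yet
  st <- MAseg:::plateauStep(st, 0.5, 5L, 0.1) # fifth stall
  expect_equal(st$lr, 1e-4)
  expect_equal(st$since, 0L)
})

test_that("training runs, improves, and honours degenerate maxEpochs = 0", {
  b <- makeFixtureSet(3, seed = 21, specRanges = list(
    frameSize = 32, nFrames = 6, bodyDiameter = c(8, 12),
    vesselWidth = c(3, 4), shapes = "disk"
  ))
  pairs <- lapply(b, function(x) rawPair(x@mask))
  net <- buildNetwork(networkConfig("tiny"), seed = 1)
  fit0 <- trainModel(pairs[1:2], pairs[3], net, trainConfig(maxEpochs = 0))
  expect_identical(fit0$net@params, net@params)
  expect_equal(nrow(fit0$history), 0)
  fit <- trainModel(pairs[1:2], pairs[3], net,
    trainConfig(maxEpochs = 6, batchSize = 2, inputSize = 32, seed = 2))
  expect_equal(nrow(fit$history), 6)
  expect_lt(fit$history$trainLoss[6], fit$history$trainLoss[1])
  expect_true(all(is.finite(fit$history$valLoss)))
})
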