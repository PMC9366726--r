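test_that("binarization follows the >= 0.5 convention and is idempotent", {
  expect_equal(binarize(matrix(0.6, 4, 4))@image, matrix(1, 4, 4))
  expect_equal(binarize(matrix(0.4, 4, 4))@image, matrix(0, 4, 4))
  expect_equal(binarize(matrix(0.5, 2, 2))@image, matrix(1, 2, 2))
  expect_error(binarize(matrix(0.5, 2, 2), threshold = 1), "threshold")
  expect_error(binarize(matrix(0.5, 2, 2), threshold = 0), "threshold")
  # idempotence on its own output embedded as {eps, 1-eps}
  p <- matrix(withSeed(1, runif(64)), 8, 8)
  m1 <- binarize(p)
  embedded <- clamp(m1@image, 1e-6, 1 - 1e-6)
  expect_identical(binarize(embedded)@image, m1@image)
})

test_that("fragment clearing matches a flood-fill oracle on random masks", {
  for (seed in 1:4) {
    m <- matrix(withSeed(seed, rbinom(64 * 64, 1, 0.25)), 64, 64)
    for (minArea in c(5, 20)) {
      got <- clearFragments(binaryMask(m), minArea)@image
      lab <- floodFillLabels(m)
      keepLab <- which(tabulate(lab[lab > 0]) >= minArea)
      oracle <- matrix(as.numeric(lab %in% keepLab & lab > 0), 64, 64)
      expect_identical(got, oracle)
    }
  }
})

test_that("area threshold boundary: >= minArea kept, below removed", {
  m <- matrix(0, 80, 80)
  m[2:26, 2:42] <- 1 # 25 x 41 = 1025 px
  m[40:71, 2:33] <- 1 # 32 x 32 = 1024 px
  m[75:78, 60:63] <- 1 # 16 px fragment
  out <- clearFragments(binaryMask(m), 1024)@image
  expect_equal(sum(out[2:26, 2:42]), 1025)
  expect_equal(sum(out[40:71, 2:33]), 1024) # exactly 1024: retained
  expect_equal(sum(out[75:78, 60:63]), 0)
  # 1023 px component is removed
  m2 <- matrix(0, 80, 80)
  m2[2:32, 2:34] <- 1 # 31 x 33 = 1023 px
  expect_equal(sum(m2), 1023)
  expect_equal(sum(clearFragments(binaryMask(m2), 1024)@image), 0)
  # empty mask passes through
  empty <- binaryMask(matrix(0, 8, 8))
  expect_identical(clearFragments(empty, 1024)@image, empty@image)
  # clearing never increases foreground
  r <- matrix(withSeed(9, rbinom(900, 1, 0.4)), 30, 30)
  expect_lte(sum(clearFragments(binaryMask(r), 10)@image), sum(r))
})

test_that("ensemble selection ranks by score with index tie-breaks", {
  spec <- ensembleSpec(nModels = 5, nSelected = 3)
  expect_equal(selectModels(c(0.2, 0.9, 0.9, 0.1, 0.5), spec), c(2, 3, 5))
  specLoss <- ensembleSpec(nModels = 5, nSelected = 2, selectionMetric = "loss")
  expect_equal(selectModels(c(0.3, 0.1, 0.1, 0.5, 0.2), specLoss), c(2, 3))
  expect_error(selectModels(c(0.1, 0.2), spec), "5")
  expect_error(ensembleSpec(nModels = 2, nSelected = 3), "nSelected")
})

test_that("union of selected masks obeys OR algebra", {
  mk <- function(rows) {
    m <- matrix(0, 8, 8)
    m[rows, ] <- 1
    binaryMask(m)
  }
  same <- replicate(4, mk(2:3), simplify = FALSE)
  spec <- ensembleSpec(nModels = 4, nSelected = 3)
  u <- selectAndUnion(same, c(0.9, 0.8, 0.7, 0.6), spec)
  expect_identical(u@image, same[[1]]@image) # idempotence
  disjoint <- list(mk(1), mk(3), mk(5), mk(7))
  u2 <- selectAndUnion(disjoint, c(0.9, 0.8, 0.7, 0.1), spec)
  lab <- floodFillLabels(u2@image)
  expect_equal(max(lab), 3) # three disjoint blobs survive
  # an all-zero selected member leaves the union unchanged
  withZero <- list(mk(1), mk(3), binaryMask(matrix(0, 8, 8)), mk(7))
  u3 <- selectAndUnion(withZero, c(0.9, 0.8, 0.7, 0.1), spec)
  expect_identical(u3@image, pmax(mk(1)@image, mk(3)@image))
  # union never decreases foreground relative to any selected member
  for (i in 1:3) expect_true(all(u2@image >= disjoint[[i]]@image))
  expect_error(selectAndUnion(disjoint, c(0.1, 0.2), spec), "lengths")
})
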