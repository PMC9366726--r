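# Encoder-decoder segmentation network, composite loss, data split and
# training loop. The network is a 5-level U-shape: each encoder block halves
# the resolution (max-pool) and applies two 3x3 conv+ReLU layers; each
# decoder block upsamples x2, concatenates the matching encoder skip and
# applies two 3x3 conv+ReLU layers; a 1x1 convolution plus sigmoid yields a
# per-pixel probability. Backpropagation and Adam are implemented here
# directly (no deep-learning framework is available in the target library),
# with convolutions delegated to compiled im2col/GEMM primitives.

#' SegmentationNetwork: a U-shaped encoder-decoder model
#'
#' @slot config the [networkConfig()] list the network was built from.
#' @slot params named list of layer weights (`w`: `(k^2*Cin) x Cout` matrix,
#'   `b`: length-`Cout` bias).
#' @export
setClass("SegmentationNetwork", representation(config = "list", params = "list"))

setMethod("show", "SegmentationNetwork", function(object) {
  np <- sum(vapply(object@params, function(l) length(l$w) + length(l$b), numeric(1)))
  cat(sprintf(
    "SegmentationNetwork: encoder '%s' (depth %d), decoder channels (%s), %d parameters\n",
    object@config$encoder, object@config$encoderDepth,
    paste(object@config$decoderChannels, collapse = ", "), np
  ))
})

#' Network configuration
#'
#' The full-scale model mirrors a UNet with an EfficientNet-b3-class encoder
#' of depth 5 and decoder channels (256, 128, 64, 32, 16). Offline, encoder
#' `"efficientnet-b3"` maps to a plain-convolution encoder of comparable
#' widths (no pretrained weights are obtainable without a network); encoder
#' `"tiny"` preserves the 5-level U-shape at widths small enough to train on
#' a CPU and is what the test suite exercises.
#'
#' @param encoder `"tiny"`, `"large"` or `"efficientnet-b3"` (alias of
#'   `"large"`).
#' @param encoderDepth number of encoder levels (5).
#' @param decoderChannels integer vector, one width per decoder block; must
#'   have length `encoderDepth`. Defaults depend on the encoder preset.
#' @param inChannels input channels (2: enhanced + perfusion).
#' @param pretrained must be `FALSE`: pretrained encoder weights cannot be
#'   downloaded in an offline build.
#' @return A named list of class `NetworkConfig`.
#' @export
networkConfig <- function(encoder = "tiny", encoderDepth = 5L,
                          decoderChannels = NULL, inChannels = 2L,
                          pretrained = FALSE) {
  if (isTRUE(pretrained)) {
    stop("pretrained encoder weights are not available in an offline build")
  }
  if (encoder == "efficientnet-b3") {
    message(
      "offline build: 'efficientnet-b3' maps to a plain-convolution ",
      "encoder of comparable widths (no pretrained weights available)"
    )
  }
  enc <- switch(encoder,
    tiny = c(8L, 16L, 24L, 32L, 40L),
    large = ,
    `efficientnet-b3` = c(40L, 80L, 160L, 320L, 640L),
    stop("unknown encoder preset: ", encoder)
  )
  if (is.null(decoderChannels)) {
    decoderChannels <- switch(encoder,
      tiny = c(32L, 24L, 16L, 12L, 8L),
      c(256L, 128L, 64L, 32L, 16L)
    )
  }
  if (length(decoderChannels) != encoderDepth) {
    stop("decoderChannels must have one entry per encoder level")
  }
  if (length(enc) != encoderDepth) stop("encoder preset depth mismatch")
  structure(
    list(
      encoder = encoder, encoderDepth = as.integer(encoderDepth),
      encoderChannels = enc, decoderChannels = as.integer(decoderChannels),
      inChannels = as.integer(inChannels), pretrained = FALSE
    ),
    class = "NetworkConfig"
  )
}

heInit <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), k * k * cin, cout)
}

#' Build a segmentation network with seeded initialization
#'
#' @param config a [networkConfig()].
#' @param seed integer; two builds with the same config and seed have
#'   identical initial parameters.
#' @return A [SegmentationNetwork-class].
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
  e <- config$encoderChannels
  d <- config$decoderChannels
  depth <- config$encoderDepth
  params <- withSeed(seed, {
    p <- list()
    cin <- config$inChannels
    for (i in seq_len(depth)) {
      p[[paste0("enc", i, "a")]] <- list(w = heInit(3, cin, e[i]), b = numeric(e[i]))
      p[[paste0("enc", i, "b")]] <- list(w = heInit(3, e[i], e[i]), b = numeric(e[i]))
      cin <- e[i]
    }
    u <- e[depth]
    for (j in seq_len(depth)) {
      skip <- if (depth - j >= 1) e[depth - j] else 0L
      p[[paste0("dec", j, "a")]] <- list(w = heInit(3, u + skip, d[j]), b = numeric(d[j]))
      p[[paste0("dec", j, "b")]] <- list(w = heInit(3, d[j], d[j]), b = numeric(d[j]))
      u <- d[j]
    }
    p[["head"]] <- list(w = heInit(1, d[depth], 1L), b = numeric(1))
    p
  })
  new("SegmentationNetwork", config = unclass(config), params = params)
}

catChannels <- function(a, b) {
  out <- array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out
}

# Forward pass; with cache = TRUE all intermediates needed by netBackward
# are retained.
netForward <- function(net, x, cache = FALSE) {
  p <- net@params
  depth <- net@config$encoderDepth
  if (any(dim(x)[1:2] %% 2^depth != 0)) {
    stop("input size must be divisible by ", 2^depth)
  }
  encActs <- vector("list", depth)
  encCache <- vector("list", depth)
  a <- x
  for (i in seq_len(depth)) {
    mp <- cpp_maxpool_fwd(a)
    wa <- p[[paste0("enc", i, "a")]]
    wb <- p[[paste0("enc", i, "b")]]
    z1 <- cpp_conv_fwd(mp$y, wa$w, wa$b, 3L)
    r1 <- pmax(z1, 0)
    z2 <- cpp_conv_fwd(r1, wb$w, wb$b, 3L)
    a2 <- pmax(z2, 0)
    encActs[[i]] <- a2
    if (cache) {
      encCache[[i]] <- list(
        idx = mp$idx, inH = dim(a)[1], inW = dim(a)[2],
        pooled = mp$y, r1 = r1
      )
    }
    a <- a2
  }
  decCache <- vector("list", depth)
  u <- a
  for (j in seq_len(depth)) {
    uu <- cpp_upsample2_fwd(u)
    hasSkip <- depth - j >= 1
    inp <- if (hasSkip) catChannels(uu, encActs[[depth - j]]) else uu
    wa <- p[[paste0("dec", j, "a")]]
    wb <- p[[paste0("dec", j, "b")]]
    z1 <- cpp_conv_fwd(inp, wa$w, wa$b, 3L)
    r1 <- pmax(z1, 0)
    z2 <- cpp_conv_fwd(r1, wb$w, wb$b, 3L)
    u2 <- pmax(z2, 0)
    if (cache) {
      decCache[[j]] <- list(
        inp = inp, r1 = r1, u2 = u2, upChannels = dim(uu)[3], hasSkip = hasSkip
      )
    }
    u <- u2
  }
  wh <- p[["head"]]
  logit <- cpp_conv_fwd(u, wh$w, wh$b, 1L)
  prob <- 1 / (1 + exp(-logit[, , 1]))
  if (!cache) {
    return(list(prob = prob))
  }
  list(
    prob = prob, x = x, encActs = encActs, encCache = encCache,
    decCache = decCache, uFinal = u
  )
}

# Backward pass from dL/dprob; returns gradients named like net@params.
netBackward <- function(net, fw, gProb) {
  p <- net@params
  depth <- net@config$encoderDepth
  grads <- list()
  prob <- fw$prob
  gLogit <- gProb * prob * (1 - prob)
  gLogitCube <- array(gLogit, c(dim(gLogit), 1L))
  bh <- cpp_conv_bwd(fw$uFinal, p[["head"]]$w, gLogitCube, 1L)
  grads[["head"]] <- list(gw = bh$gw, gb = bh$gb)
  gu <- bh$gx
  gEnc <- vector("list", depth) # accumulated grads w.r.t. encoder activations
  for (j in seq(depth, 1)) {
    dc <- fw$decCache[[j]]
    wb <- p[[paste0("dec", j, "b")]]
    wa <- p[[paste0("dec", j, "a")]]
    gz2 <- gu * (dc$u2 > 0)
    b2 <- cpp_conv_bwd(dc$r1, wb$w, gz2, 3L)
    grads[[paste0("dec", j, "b")]] <- list(gw = b2$gw, gb = b2$gb)
    gz1 <- b2$gx * (dc$r1 > 0)
    b1 <- cpp_conv_bwd(dc$inp, wa$w, gz1, 3L)
    grads[[paste0("dec", j, "a")]] <- list(gw = b1$gw, gb = b1$gb)
    gInp <- b1$gx
    nu <- dc$upChannels
    gUp <- gInp[, , seq_len(nu), drop = FALSE]
    if (dc$hasSkip) {
      gSkip <- gInp[, , -seq_len(nu), drop = FALSE]
      k <- depth - j
      gEnc[[k]] <- if (is.null(gEnc[[k]])) gSkip else gEnc[[k]] + gSkip
    }
    gu <- cpp_upsample2_bwd(gUp)
  }
  # gu now holds the gradient w.r.t. the bottleneck activation (enc depth)
  gEnc[[depth]] <- if (is.null(gEnc[[depth]])) gu else gEnc[[depth]] + gu
  gBelow <- NULL
  for (i in seq(depth, 1)) {
    ec <- fw$encCache[[i]]
    ga <- gEnc[[i]]
    if (!is.null(gBelow)) ga <- ga + gBelow
    wb <- p[[paste0("enc", i, "b")]]
    wa <- p[[paste0("enc", i, "a")]]
    a2 <- fw$encActs[[i]]
    gz2 <- ga * (a2 > 0)
    b2 <- cpp_conv_bwd(ec$r1, wb$w, gz2, 3L)
    grads[[paste0("enc", i, "b")]] <- list(gw = b2$gw, gb = b2$gb)
    gz1 <- b2$gx * (ec$r1 > 0)
    b1 <- cpp_conv_bwd(ec$pooled, wa$w, gz1, 3L)
    grads[[paste0("enc", i, "a")]] <- list(gw = b1$gw, gb = b1$gb)
    gPool <- cpp_maxpool_bwd(ec$idx, b1$gx, ec$inH, ec$inW)
    gBelow <- if (i > 1) gPool else NULL
  }
  grads
}

#' Loss configuration
#'
#' @param alpha weight of the Dice term in `BCE + alpha * (1 - softDice)`
#'   (0.2 equalizes the two contributions at full scale).
#' @param clipEps probabilities are clipped to `[clipEps, 1 - clipEps]`
#'   before the logarithms.
#' @return A named list of class `LossConfig`.
#' @export
lossConfig <- function(alpha = 0.2, clipEps = 1e-7) {
  stopifnot(alpha >= 0, clipEps > 0, clipEps < 0.5)
  structure(list(alpha = alpha, clipEps = clipEps), class = "LossConfig")
}

lossAndGrad <- function(prob, target, cfg) {
  if (!identical(dim(prob), dim(target))) stop("prediction/target shape mismatch")
  eps <- cfg$clipEps
  x <- clamp(prob, eps, 1 - eps)
  y <- target
  n <- length(x)
  bce <- -mean(y * log(x) + (1 - y) * log(1 - x))
  sxy <- sum(x * y)
  den <- sum(x) + sum(y) + 1
  dice <- (2 * sxy + 1) / den
  loss <- bce + cfg$alpha * (1 - dice)
  inside <- (prob > eps) & (prob < 1 - eps)
  gBce <- ((1 - y) / (1 - x) - y / x) / n
  gDice <- 2 * y / den - (2 * sxy + 1) / den^2
  g <- (gBce - cfg$alpha * gDice) * inside
  list(loss = loss, grad = g, bce = bce, dice = dice)
}

#' Composite segmentation loss: BCE plus weighted soft Dice
#'
#' `loss = BCE + alpha * (1 - softDice)` where BCE is the negative mean
#' per-pixel binary cross-entropy of the (clipped) probabilities and softDice
#' uses probabilities directly, `(2*sum(x*y) + 1) / (sum(x) + sum(y) + 1)`,
#' with smoothing constant 1 so empty masks are well-defined. The loss is
#' zero in the perfect-prediction limit as `clipEps -> 0`.
#'
#' @param pred a [ProbabilityMap-class] or numeric matrix in (0, 1).
#' @param target a [BinaryMask-class] or 0/1 matrix of the same shape.
#' @param config a [lossConfig()].
#' @return Nonnegative scalar loss.
#' @export
compositeLoss <- function(pred, target, config = lossConfig()) {
  x <- if (is(pred, "ProbabilityMap")) pred@image else pred
  y <- if (is(target, "BinaryMask")) target@image else target
  lossAndGrad(x, y, config)$loss
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam with learning rate 0.001 and
#' weight decay 1e-8, batch size 16, up to 200 epochs, and a plateau
#' scheduler that multiplies the learning rate by 0.1 once the validation
#' loss has not decreased for 5 epochs. Tests override `inputSize`,
#' `maxEpochs` and `batchSize` to CPU scale.
#'
#' @param lr initial learning rate.
#' @param weightDecay L2 weight decay added to the gradient.
#' @param maxEpochs maximum number of epochs.
#' @param batchSize minibatch size.
#' @param plateauPatience epochs of non-improving validation loss before the
#'   learning rate drops.
#' @param plateauFactor multiplicative learning-rate drop (1/10).
#' @param inputSize square input side in px (512 at full scale).
#' @param seed integer seed for shuffling.
#' @return A named list of class `TrainConfig`.
#' @export
trainConfig <- function(lr = 0.001, weightDecay = 1e-8, maxEpochs = 200L,
                        batchSize = 16L, plateauPatience = 5L,
                        plateauFactor = 0.1, inputSize = 512L, seed = 1L) {
  stopifnot(lr > 0, weightDecay >= 0, maxEpochs >= 0, batchSize >= 1,
    plateauPatience >= 1, plateauFactor > 0, plateauFactor < 1)
  structure(
    list(
      lr = lr, weightDecay = weightDecay, maxEpochs = as.integer(maxEpochs),
      batchSize = as.integer(batchSize),
      plateauPatience = as.integer(plateauPatience),
      plateauFactor = plateauFactor, inputSize = as.integer(inputSize),
      seed = as.integer(seed)
    ),
    class = "TrainConfig"
  )
}

# plateau scheduler step: state is list(best, since, lr); returns updated
# state with lr dropped by `factor` after `patience` non-improving epochs
plateauStep <- function(state, valLoss, patience, factor) {
  if (valLoss < state$best - 1e-12) {
    state$best <- valLoss
    state$since <- 0L
    state$improved <- TRUE
  } else {
    state$since <- state$since + 1L
    state$improved <- FALSE
    if (state$since >= patience) {
      state$lr <- state$lr * factor
      state$since <- 0L
    }
  }
  state
}

adamInit <- function(params) {
  lapply(params, function(l) {
    list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adamStep <- function(params, grads, state, lr, wd, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    gw <- grads[[nm]]$gw + wd * params[[nm]]$w
    gb <- grads[[nm]]$gb + wd * params[[nm]]$b
    st <- state[[nm]]
    st$mw <- beta1 * st$mw + (1 - beta1) * gw
    st$vw <- beta2 * st$vw + (1 - beta2) * gw^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    c1 <- 1 - beta1^t
    c2 <- 1 - beta2^t
    params[[nm]]$w <- params[[nm]]$w - lr * (st$mw / c1) / (sqrt(st$vw / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

pairToXY <- function(pair) {
  x <- if (is(pair$image, "TwoChannelImage")) imageData(pair$image) else pair$image
  y <- if (is(pair$mask, "BinaryMask")) pair$mask@image else pair$mask
  list(x = x, y = y)
}

#' Train a segmentation network
#'
#' Minibatch Adam on the composite loss with a validation-plateau learning
#' rate schedule; returns the checkpoint with the best validation loss and a
#' per-epoch history.
#'
#' @param trainPairs nonempty list of `list(image, mask)` training pairs.
#' @param valPairs nonempty list of validation pairs.
#' @param net a [SegmentationNetwork-class] (seeded initial state).
#' @param config a [trainConfig()].
#' @param lossCfg a [lossConfig()].
#' @param verbose print per-epoch progress.
#' @return list with `net` (best-validation checkpoint), `history`
#'   (data.frame epoch/trainLoss/valLoss/lr) and `bestValLoss`.
#' @export
trainModel <- function(trainPairs, valPairs, net, config = trainConfig(),
                       lossCfg = lossConfig(), verbose = FALSE) {
  if (config$maxEpochs == 0) {
    return(list(
      net = net,
      history = data.frame(
        epoch = integer(0), trainLoss = numeric(0),
        valLoss = numeric(0), lr = numeric(0)
      ),
      bestValLoss = NA_real_
    ))
  }
  if (length(trainPairs) == 0 || length(valPairs) == 0) {
    stop("train and validation sets must be nonempty")
  }
  tr <- lapply(trainPairs, pairToXY)
  va <- lapply(valPairs, pairToXY)
  params <- net@params
  adam <- adamInit(params)
  sched <- list(best = Inf, since = 0L, lr = config$lr, improved = FALSE)
  bestParams <- params
  bestVal <- Inf
  hist <- vector("list", config$maxEpochs)
  t <- 0
  tmpNet <- net
  for (epoch in seq_len(config$maxEpochs)) {
    lrEpoch <- sched$lr
    ord <- withSeed(
      deriveSeed(config$seed, paste0("epoch-", epoch)),
      sample(length(tr))
    )
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0
    tmpNet@params <- params
    for (bt in batches) {
      gacc <- NULL
      for (ix in bt) {
        fw <- netForward(tmpNet, tr[[ix]]$x, cache = TRUE)
        lg <- lossAndGrad(fw$prob, tr[[ix]]$y, lossCfg)
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (lr %g)",
            epoch, lrEpoch
          ))
        }
        epochLoss <- epochLoss + lg$loss
        g <- netBackward(tmpNet, fw, lg$grad)
        if (is.null(gacc)) {
          gacc <- g
        } else {
          for (nm in names(g)) {
            gacc[[nm]]$gw <- gacc[[nm]]$gw + g[[nm]]$gw
            gacc[[nm]]$gb <- gacc[[nm]]$gb + g[[nm]]$gb
          }
        }
      }
      for (nm in names(gacc)) {
        gacc[[nm]]$gw <- gacc[[nm]]$gw / length(bt)
        gacc[[nm]]$gb <- gacc[[nm]]$gb / length(bt)
      }
      t <- t + 1
      upd <- adamStep(params, gacc, adam, lrEpoch, config$weightDecay, t)
      params <- upd$params
      adam <- upd$state
      tmpNet@params <- params
    }
    trainLoss <- epochLoss / length(tr)
    valLoss <- mean(vapply(va, function(pp) {
      fw <- netForward(tmpNet, pp$x, cache = FALSE)
      lossAndGrad(fw$prob, pp$y, lossCfg)$loss
    }, numeric(1)))
    if (!is.finite(valLoss)) {
      stop(sprintf("training diverged: non-finite validation loss at epoch %d", epoch))
    }
    sched <- plateauStep(sched, valLoss, config$plateauPatience, config$plateauFactor)
    if (sched$improved) {
      bestParams <- params
      bestVal <- valLoss
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, trainLoss = trainLoss, valLoss = valLoss, lr = lrEpoch
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train %.4f  val %.4f  lr %g", epoch, trainLoss, valLoss, lrEpoch
      ))
    }
  }
  out <- net
  out@params <- bestParams
  list(net = out, history = do.call(rbind, hist), bestValLoss = bestVal)
}

#' Predict a probability map for a two-channel image
#'
#' Deterministic inference; output values lie strictly inside (0, 1).
#'
#' @param net a [SegmentationNetwork-class].
#' @param image a [TwoChannelImage-class] (or `(H, W, 2)` array) with sides
#'   divisible by 32.
#' @return A [ProbabilityMap-class] of the input spatial shape.
#' @export
predictMap <- function(net, image) {
  x <- if (is(image, "TwoChannelImage")) imageData(image) else image
  if (length(dim(x)) != 3 || dim(x)[3] != net@config$inChannels) {
    stop("expected a (H, W, ", net@config$inChannels, ") input")
  }
  prob <- netForward(net, x, cache = FALSE)$prob
  probabilityMap(clamp(prob, 1e-12, 1 - 1e-12))
}

#' Save a trained network checkpoint
#'
#' Writes the network in R's native serialized format plus a JSON sidecar
#' holding the network config and, when supplied, the training history.
#'
#' @param net a [SegmentationNetwork-class].
#' @param path output `.rds` path (sidecar written next to it as `.json`).
#' @param history optional per-epoch history data.frame from [trainModel()].
#' @return The checkpoint path, invisibly.
#' @export
saveCheckpoint <- function(net, path, history = NULL) {
  saveRDS(net, path)
  sidecar <- list(config = net@config)
  if (!is.null(history)) sidecar$history <- history
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Load a network checkpoint written by [saveCheckpoint()]
#' @param path checkpoint `.rds` path.
#' @return A [SegmentationNetwork-class].
#' @export
loadCheckpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(is(net, "SegmentationNetwork"))
  net
}

#' Reserve a test fold and build 10 cross-validation folds
#'
#' One fifth of the ids (`floor(n/5)`) is reserved for testing; the
#' remaining pool is split into 10 folds as equal as possible, each fold
#' serving once as validation. For 87 ids this reproduces the
#' train:validation:test split 63:7:17.
#'
#' @param ids vector of at least 15 image ids.
#' @param seed integer seed; the split is deterministic under it.
#' @param nFolds number of cross-validation folds over the pool.
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(ids, seed = 1L, nFolds = 10L) {
  n <- length(ids)
  if (n < 15) stop("need at least 15 ids to split")
  perm <- withSeed(deriveSeed(seed, "split"), sample(n))
  nTest <- floor(n / 5)
  testIds <- ids[perm[seq_len(nTest)]]
  pool <- ids[perm[-seq_len(nTest)]]
  m <- length(pool)
  sizes <- rep(floor(m / nFolds), nFolds)
  extra <- m - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1) + 1L)
  folds <- lapply(seq_len(nFolds), function(k) {
    val <- pool[seq(starts[k], stops[k])]
    list(train = setdiff(pool, val), val = val)
  })
  new("SplitPlan", testIds = testIds, folds = folds)
}
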