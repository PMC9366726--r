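# End-to-end orchestration: phantom -> preprocess -> augment -> train ->
# predict -> postprocess -> evaluate -> morphometry, with one global seed
# feeding named per-stage substreams, artifact writing and a hashed
# manifest so deterministic stages reproduce bit-for-bit.

#' Pipeline configuration
#'
#' Bundles every stage's parameters behind one object. All module
#' parameters are reachable here and the object round-trips through JSON
#' serialization unchanged. Defaults describe the CPU demo scale (8
#' phantoms, tiny encoder, 64 px inputs); the full-scale recipe uses
#' `inputSize = 512`, `augment$nRotations = 32`, `train$maxEpochs = 200`.
#'
#' @param outDir run directory for artifacts.
#' @param seed global integer seed; all stage randomness derives from it.
#' @param nPhantoms number of phantom images to generate.
#' @param inputSize network input side (px); phantom frames default to the
#'   same size so morphometry truth stays in input pixels.
#' @param phantom named list overriding [makeFixtureSet()] spec ranges.
#' @param window local-mean window of the enhanced image.
#' @param enhance named list overriding [enhanceParams()].
#' @param augment named list overriding [augmentConfig()] (seed is derived).
#' @param network named list overriding [networkConfig()].
#' @param train named list overriding [trainConfig()] (inputSize/seed derived).
#' @param postprocess `threshold` and `minArea`; `minArea` defaults to the
#'   full-scale 1024 px rescaled by `(inputSize/512)^2`.
#' @param morphometry `k` and `pruneLen` for [morphometry()].
#' @param ensemble named list overriding [ensembleSpec()] (for
#'   [runCvEnsemble()]).
#' @return A named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir = tempfile("maseg-run-"), seed = 1L,
                           nPhantoms = 8L, inputSize = 64L,
                           phantom = list(), window = 5L, enhance = list(),
                           augment = list(nRotations = 4L),
                           network = list(encoder = "tiny"),
                           train = list(maxEpochs = 5L, batchSize = 8L),
                           postprocess = list(), morphometry = list(),
                           ensemble = list()) {
  pp <- list(
    threshold = 0.5,
    minArea = max(1, round(1024 * (inputSize / 512)^2))
  )
  for (nm in names(postprocess)) pp[[nm]] <- postprocess[[nm]]
  mm <- list(k = 10L, pruneLen = 3L)
  for (nm in names(morphometry)) mm[[nm]] <- morphometry[[nm]]
  structure(
    list(
      outDir = outDir, seed = as.integer(seed),
      nPhantoms = as.integer(nPhantoms), inputSize = as.integer(inputSize),
      phantom = phantom, window = as.integer(window), enhance = enhance,
      augment = augment, network = network, train = train,
      postprocess = pp, morphometry = mm, ensemble = ensemble
    ),
    class = "PipelineConfig"
  )
}

#' Serialize a pipeline config to JSON
#' @param config a [pipelineConfig()].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}

#' Read a pipeline config from JSON
#' @param path JSON path written by [writePipelineConfig()].
#' @return A [pipelineConfig()] equal to the one serialized.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$phantom <- as.list(raw$phantom)
  raw$enhance <- as.list(raw$enhance)
  raw$augment <- as.list(raw$augment)
  raw$network <- as.list(raw$network)
  raw$train <- as.list(raw$train)
  raw$postprocess <- as.list(raw$postprocess)
  raw$morphometry <- as.list(raw$morphometry)
  raw$ensemble <- as.list(raw$ensemble)
  do.call(pipelineConfig, raw)
}

stageLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...))
}

# phantom + preprocess stages shared by runPipeline and runCvEnsemble
preparePhantomData <- function(config, verbose = FALSE) {
  size <- config$inputSize
  ranges <- config$phantom
  if (is.null(ranges$frameSize)) ranges$frameSize <- size
  stageLog(verbose, "phantom: generating %d bundles", config$nPhantoms)
  bundles <- makeFixtureSet(config$nPhantoms, deriveSeed(config$seed, "phantom"), ranges)
  ep <- do.call(enhanceParams, config$enhance)
  stageLog(verbose, "preprocess: %d videos -> two-channel %dpx", length(bundles), size)
  pairs <- lapply(bundles, function(b) {
    pre <- preprocessVideo(b@video, size = size, window = config$window, params = ep)
    list(
      image = pre$twoChannel,
      mask = resizeMask(b@mask, size),
      perfusion = pre$perfusion, enhanced = pre$enhanced
    )
  })
  list(bundles = bundles, pairs = pairs)
}

writeRunArtifacts <- function(dir, bundles, pairs) {
  pdir <- file.path(dir, "phantom")
  idir <- file.path(dir, "preprocess")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(idir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bundles)) {
    nm <- sprintf("img%03d", i)
    writePhantomBundle(bundles[[i]], pdir, nm)
    writeTwoChannelTIFF(pairs[[i]]$image, file.path(idir, paste0(nm, "_2ch.tif")))
    writeMaskPGM(pairs[[i]]$mask, file.path(idir, paste0(nm, "_mask.pgm")))
  }
}

writeManifest <- function(dir, config, extra = list()) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- sub(paste0("^", dir, "/?"), "", names(hashes))
  manifest <- c(
    list(
      package = "MAseg",
      version = as.character(utils::packageVersion("MAseg")),
      seed = config$seed, config = unclass(config), files = hashes
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

morphometryVsTruth <- function(masks, bundles, ids, mm) {
  rows <- list()
  for (j in seq_along(ids)) {
    i <- ids[j]
    truth <- bundles[[i]]@truth
    rep <- tryCatch(
      morphometry(masks[[j]], k = mm$k, pruneLen = mm$pruneLen),
      error = function(e) NULL
    )
    if (is.null(rep) || nrow(truth) != 1) next
    tab <- morphometryTable(rep)
    main <- tab[which.max(tab$area), ]
    rows[[length(rows) + 1]] <- data.frame(
      id = i, lc = main$lc, nc = main$nc, bnr = main$bnr,
      trueLc = truth$diameter, trueNc = truth$minVesselWidth, trueBnr = truth$bnr
    )
  }
  do.call(rbind, rows)
}

#' Run the pipeline end to end on phantom data
#'
#' Generates phantoms, preprocesses them into two-channel inputs, augments
#' the training split, trains the network, predicts and postprocesses the
#' held-out test split, scores Dice/IoU, and quantifies morphometry against
#' the construction truth. All artifacts are written under
#' `config$outDir` with an md5 manifest; rerunning with the same config and
#' seed reproduces the deterministic artifacts bit-for-bit.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with `scores`, `morph`, `mse`, `history`,
#'   `outDir` and the trained `net`.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  prep <- preparePhantomData(config, verbose)
  writeRunArtifacts(config$outDir, prep$bundles, prep$pairs)
  n <- length(prep$pairs)
  # holdout split at demo scale: ~1/5 test, ~1/10 of the rest validation
  idx <- withSeed(deriveSeed(config$seed, "holdout"), sample(n))
  nTest <- max(1, floor(n / 5))
  nVal <- max(1, floor((n - nTest) / 10))
  testIds <- idx[seq_len(nTest)]
  valIds <- idx[nTest + seq_len(nVal)]
  trainIds <- setdiff(idx, c(testIds, valIds))
  if (length(trainIds) == 0) stop("too few phantoms to split")
  augCfg <- do.call(augmentConfig, c(config$augment,
    list(seed = deriveSeed(config$seed, "augment"))))
  stageLog(verbose, "augment: %d train images x %d rotations", length(trainIds),
    augCfg$nRotations)
  trainSet <- augmentSet(prep$pairs[trainIds], augCfg)
  net <- buildNetwork(do.call(networkConfig, config$network),
    seed = deriveSeed(config$seed, "init"))
  trCfg <- do.call(trainConfig, c(config$train,
    list(inputSize = config$inputSize, seed = deriveSeed(config$seed, "train"))))
  stageLog(verbose, "train: %d pairs, %d epochs", length(trainSet), trCfg$maxEpochs)
  fit <- trainModel(trainSet, prep$pairs[valIds], net, trCfg, verbose = verbose)
  stageLog(verbose, "predict/postprocess: %d test images", length(testIds))
  outMaskDir <- file.path(config$outDir, "predictions")
  dir.create(outMaskDir, showWarnings = FALSE, recursive = TRUE)
  predMasks <- lapply(seq_along(testIds), function(j) {
    i <- testIds[j]
    prob <- predictMap(fit$net, prep$pairs[[i]]$image)
    writeImageTIFF(prob@image, file.path(outMaskDir, sprintf("test%03d_prob.tif", i)))
    m <- clearFragments(
      binarize(prob, config$postprocess$threshold),
      config$postprocess$minArea
    )
    writeMaskPGM(m, file.path(outMaskDir, sprintf("test%03d_mask.pgm", i)))
    m
  })
  truthMasks <- lapply(testIds, function(i) prep$pairs[[i]]$mask)
  scores <- scoreMasks(predMasks, truthMasks, ids = testIds)
  write.csv(scores, file.path(config$outDir, "scores.csv"), row.names = FALSE)
  morph <- morphometryVsTruth(predMasks, prep$bundles, testIds, config$morphometry)
  mseOut <- if (!is.null(morph) && nrow(morph) > 0) {
    list(lc = mse(morph$lc, morph$trueLc), nc = mse(morph$nc, morph$trueNc))
  } else {
    list(lc = NA_real_, nc = NA_real_)
  }
  if (!is.null(morph) && nrow(morph) > 0) {
    write.csv(morph, file.path(config$outDir, "morphometry.csv"), row.names = FALSE)
  }
  jsonlite::write_json(mseOut, file.path(config$outDir, "mse.json"),
    auto_unbox = TRUE, digits = NA)
  if (nrow(fit$history) > 0) {
    write.csv(fit$history, file.path(config$outDir, "history.csv"), row.names = FALSE)
  }
  writeManifest(config$outDir, config,
    extra = list(split = list(train = trainIds, val = valIds, test = testIds)))
  invisible(list(
    scores = scores, morph = morph, mse = mseOut, history = fit$history,
    outDir = config$outDir, net = fit$net
  ))
}

#' Cross-validated ensemble: train 10 folds, select 3, union predictions
#'
#' Reserves a test fold, trains one model per cross-validation fold, scores
#' each on its validation fold (mean Dice of the postprocessed masks, or
#' validation loss), selects the best `nSelected`, and writes the pixel-wise
#' union of their postprocessed test predictions.
#'
#' @param config a [pipelineConfig()]; needs `nPhantoms >= 15`.
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with `selected` (model indices), `valScores`,
#'   `scores` (union vs truth), `split` and `outDir`.
#' @export
runCvEnsemble <- function(config = pipelineConfig(nPhantoms = 15L), verbose = FALSE) {
  spec <- do.call(ensembleSpec, config$ensemble)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  prep <- preparePhantomData(config, verbose)
  writeRunArtifacts(config$outDir, prep$bundles, prep$pairs)
  n <- length(prep$pairs)
  plan <- makeSplit(seq_len(n), seed = deriveSeed(config$seed, "split"),
    nFolds = spec$nModels)
  postproc <- function(net, pair) {
    clearFragments(
      binarize(predictMap(net, pair$image), config$postprocess$threshold),
      config$postprocess$minArea
    )
  }
  nets <- vector("list", spec$nModels)
  valScores <- numeric(spec$nModels)
  for (k in seq_len(spec$nModels)) {
    fold <- plan@folds[[k]]
    augCfg <- do.call(augmentConfig, c(config$augment,
      list(seed = deriveSeed(config$seed, paste0("augment-fold", k)))))
    trainSet <- augmentSet(prep$pairs[fold$train], augCfg)
    net <- buildNetwork(do.call(networkConfig, config$network),
      seed = deriveSeed(config$seed, paste0("init-fold", k)))
    trCfg <- do.call(trainConfig, c(config$train,
      list(inputSize = config$inputSize,
        seed = deriveSeed(config$seed, paste0("train-fold", k)))))
    stageLog(verbose, "fold %d/%d: training on %d pairs", k, spec$nModels,
      length(trainSet))
    fit <- trainModel(trainSet, prep$pairs[fold$val], net, trCfg)
    nets[[k]] <- fit$net
    valScores[k] <- if (spec$selectionMetric == "loss") {
      fit$bestValLoss
    } else {
      mean(vapply(fold$val, function(i) {
        diceCoefficient(postproc(fit$net, prep$pairs[[i]]), prep$pairs[[i]]$mask)
      }, numeric(1)))
    }
  }
  if (sum(!vapply(nets, is.null, logical(1))) < spec$nSelected) {
    stop("fewer trained models than nSelected")
  }
  selected <- selectModels(valScores, spec)
  stageLog(verbose, "ensemble: selected models %s", paste(selected, collapse = ", "))
  edir <- file.path(config$outDir, "ensemble")
  dir.create(edir, showWarnings = FALSE, recursive = TRUE)
  unionMasks <- lapply(plan@testIds, function(i) {
    perModel <- lapply(nets, function(nt) postproc(nt, prep$pairs[[i]]))
    u <- selectAndUnion(perModel, valScores, spec)
    writeMaskPGM(u, file.path(edir, sprintf("test%03d_union.pgm", i)))
    u
  })
  truthMasks <- lapply(plan@testIds, function(i) prep$pairs[[i]]$mask)
  scores <- scoreMasks(unionMasks, truthMasks, ids = plan@testIds)
  write.csv(scores, file.path(config$outDir, "ensemble_scores.csv"), row.names = FALSE)
  writeManifest(config$outDir, config, extra = list(
    selected = selected, valScores = valScores,
    split = list(test = plan@testIds)
  ))
  invisible(list(
    selected = selected, valScores = valScores, scores = scores,
    split = plan, outDir = config$outDir, nets = nets, unionMasks = unionMasks
  ))
}
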