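# Synthetic AOSLO phantom generator.
#
# A phantom is a stated world: MA bodies of known diameter, attached
# feeding/draining vessels of known width, and free-floating distractor
# vessels, all perfused (flickering frame to frame), drawn over a static
# noisy background. As in multiply-scattered-light AOSLO frames, perfused
# lumina are DARKER than the surrounding tissue (the enhancement step
# inverts intensities, which is what makes them bright downstream); what
# identifies them in the perfusion map is the temporal flicker, not
# brightness. Geometry is rasterized on the integer pixel grid with strict
# interior tests (< radius), so even rasterized widths are exact and
# morphometry ground truth is known by construction.

#' Construct a PhantomSpec
#'
#' @param frameSize pixels per side of the square frames.
#' @param nFrames number of video frames (clinical acquisitions use 75).
#' @param maBodies list of `list(center = c(row, col), diameter,
#'   shape)` with shape `"disk"`, `"ellipse"` or `"fusiform"`.
#' @param vessels list of `list(path = 2-column matrix of (row, col)
#'   waypoints, width, attachedTo = body index or NA for a distractor)`.
#' @param flickerAmplitude temporal intensity sd of perfused pixels.
#' @param backgroundNoiseSigma sd of the frozen background texture.
#' @param intensityRange `(structure level, background level)` in `[0, 1]`:
#'   perfused structures sit at the low end, static tissue at the high end.
#' @param seed integer; fixes the phantom bit-for-bit.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(frameSize = 96L, nFrames = 75L, maBodies = list(),
                        vessels = list(), flickerAmplitude = 0.12,
                        backgroundNoiseSigma = 0.08,
                        intensityRange = c(0.35, 0.6), seed = 1L) {
  new("PhantomSpec",
    frameSize = as.integer(frameSize), nFrames = as.integer(nFrames),
    maBodies = maBodies, vessels = vessels,
    flickerAmplitude = flickerAmplitude,
    backgroundNoiseSigma = backgroundNoiseSigma,
    intensityRange = as.numeric(intensityRange), seed = as.integer(seed)
  )
}

# snap a coordinate to the parity that rasterizes an extent of `size`
# exactly: even sizes need half-integer centers, odd sizes integer centers
parityCoord <- function(x, size) {
  if (size %% 2 == 0) floor(x) + 0.5 else round(x)
}

#' Convenience spec: one disk MA with two horizontal vessels
#'
#' A disk body of `bodyDiameter` px at the frame center with a feeding and a
#' draining vessel of `vesselWidth` px running to the left and right frame
#' edges, plus one vertical distractor vessel. The construction BNR is
#' `bodyDiameter / vesselWidth`.
#'
#' @inheritParams phantomSpec
#' @param bodyDiameter MA body diameter in px.
#' @param vesselWidth attached vessel width in px.
#' @param distractor logical; add a free-floating vertical vessel.
#' @return A [PhantomSpec-class].
#' @export
diskPhantomSpec <- function(frameSize = 96L, bodyDiameter = 20,
                            vesselWidth = 5, nFrames = 75L,
                            flickerAmplitude = 0.12,
                            backgroundNoiseSigma = 0.08,
                            intensityRange = c(0.35, 0.6),
                            distractor = TRUE, seed = 1L) {
  ctr <- (frameSize + 1) / 2
  r0 <- parityCoord(ctr, bodyDiameter)
  c0 <- parityCoord(ctr, bodyDiameter)
  vr <- parityCoord(r0, vesselWidth)
  vessels <- list(
    list(path = rbind(c(vr, 1), c(vr, c0)), width = vesselWidth, attachedTo = 1L),
    list(path = rbind(c(vr, c0), c(vr, frameSize)), width = vesselWidth, attachedTo = 1L)
  )
  if (distractor) {
    dc <- parityCoord(frameSize * 0.2, vesselWidth)
    vessels <- c(vessels, list(
      list(path = rbind(c(1, dc), c(frameSize, dc)), width = vesselWidth, attachedTo = NA)
    ))
  }
  phantomSpec(
    frameSize = frameSize, nFrames = nFrames,
    maBodies = list(list(center = c(r0, c0), diameter = bodyDiameter, shape = "disk")),
    vessels = vessels, flickerAmplitude = flickerAmplitude,
    backgroundNoiseSigma = backgroundNoiseSigma,
    intensityRange = intensityRange, seed = seed
  )
}

boundingRadius <- function(body) {
  switch(body$shape,
    disk = body$diameter / 2,
    ellipse = 0.65 * body$diameter,
    fusiform = sqrt(3) / 2 * body$diameter,
    stop("unknown body shape: ", body$shape)
  )
}

rasterizeBody <- function(body, n) {
  r0 <- body$center[1]
  c0 <- body$center[2]
  d <- body$diameter
  rr <- matrix(seq_len(n), n, n) - r0
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - c0
  inside <- switch(body$shape,
    disk = rr^2 + cc^2 < (d / 2)^2,
    # semi-minor d/2 across rows (sets the caliber), semi-major 1.3x along cols
    ellipse = (rr / (d / 2))^2 + (cc / (0.65 * d))^2 < 1,
    # spindle: intersection of two circles of radius d centered d/2 off-axis;
    # inscribed radius at the center is exactly d/2
    fusiform = ((rr - d / 2)^2 + cc^2 < d^2) & ((rr + d / 2)^2 + cc^2 < d^2),
    stop("unknown body shape: ", body$shape)
  )
  inside
}

rasterizeVessel <- function(vessel, n) {
  path <- vessel$path
  w <- vessel$width
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2min <- matrix(Inf, n, n)
  for (s in seq_len(nrow(path) - 1)) {
    p1 <- path[s, ]
    p2 <- path[s + 1, ]
    v <- p2 - p1
    len2 <- sum(v^2)
    if (len2 == 0) {
      d2 <- (rr - p1[1])^2 + (cc - p1[2])^2
    } else {
      t <- clamp(((rr - p1[1]) * v[1] + (cc - p1[2]) * v[2]) / len2, 0, 1)
      d2 <- (rr - (p1[1] + t * v[1]))^2 + (cc - (p1[2] + t * v[2]))^2
    }
    d2min <- pmin(d2min, d2)
  }
  d2min < (w / 2)^2
}

#' Generate a phantom bundle from a spec
#'
#' Renders the video (perfused structures flicker i.i.d. Gaussian per frame
#' around the structure intensity; the background keeps one frozen noise
#' texture), the ground-truth mask (MA bodies plus attached vessels only) and
#' the per-MA morphometry truth. Deterministic under `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [PhantomBundle-class].
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  n <- spec@frameSize
  bodies <- spec@maBodies
  if (length(bodies) >= 2) {
    for (i in seq_len(length(bodies) - 1)) {
      for (j in seq(i + 1, length(bodies))) {
        dist <- sqrt(sum((bodies[[i]]$center - bodies[[j]]$center)^2))
        if (dist < boundingRadius(bodies[[i]]) + boundingRadius(bodies[[j]])) {
          stop("overlapping MA bodies: ground truth would be ill-posed")
        }
      }
    }
  }
  attached <- vapply(spec@vessels, function(v) !is.na(v$attachedTo), logical(1))
  if (length(bodies) > 0) {
    attachedIdx <- vapply(
      spec@vessels[attached],
      function(v) as.integer(v$attachedTo), integer(1)
    )
    if (!all(seq_along(bodies) %in% attachedIdx)) {
      stop("every MA body needs at least one attached vessel")
    }
  }
  bodyMask <- matrix(FALSE, n, n)
  for (b in bodies) bodyMask <- bodyMask | rasterizeBody(b, n)
  maskM <- bodyMask
  perfused <- bodyMask
  for (v in spec@vessels) {
    vm <- rasterizeVessel(v, n)
    perfused <- perfused | vm
    if (!is.na(v$attachedTo)) maskM <- maskM | vm
  }
  structLevel <- spec@intensityRange[1]
  bgLevel <- spec@intensityRange[2]
  nPerf <- sum(perfused)
  frames <- withSeed(spec@seed, {
    base <- matrix(bgLevel + rnorm(n * n, 0, spec@backgroundNoiseSigma), n, n)
    a <- array(0, c(n, n, spec@nFrames))
    for (f in seq_len(spec@nFrames)) {
      fr <- base
      fr[perfused] <- structLevel + rnorm(nPerf, 0, spec@flickerAmplitude)
      a[, , f] <- fr
    }
    clamp(a, 0, 1)
  })
  truth <- if (length(bodies) > 0) {
    minW <- vapply(seq_along(bodies), function(i) {
      ws <- vapply(
        spec@vessels[attached][attachedIdx == i],
        function(v) v$width, numeric(1)
      )
      min(ws)
    }, numeric(1))
    data.frame(
      body = seq_along(bodies),
      diameter = vapply(bodies, function(b) b$diameter, numeric(1)),
      minVesselWidth = minW,
      bnr = vapply(bodies, function(b) b$diameter, numeric(1)) / minW
    )
  } else {
    data.frame(
      body = integer(0), diameter = numeric(0),
      minVesselWidth = numeric(0), bnr = numeric(0)
    )
  }
  new("PhantomBundle",
    video = videoStack(frames), mask = binaryMask(maskM + 0),
    truth = truth, spec = spec
  )
}

defaultSpecRanges <- function() {
  list(
    frameSize = 96L,
    nFrames = 75L,
    # even diameters/widths: exact under the integer-grid caliber convention
    bodyDiameter = c(14, 30),
    vesselWidth = c(4, 8),
    nBodies = 1:2,
    nDistractors = 1:2,
    shapes = c("disk", "ellipse", "fusiform"),
    flickerAmplitude = 0.12,
    backgroundNoiseSigma = 0.08,
    intensityRange = c(0.35, 0.6)
  )
}

evenSeq <- function(lohi) {
  s <- seq(ceiling(lohi[1] / 2) * 2, floor(lohi[2] / 2) * 2, by = 2)
  if (length(s) == 0) stop("empty parameter range: ", paste(lohi, collapse = "-"))
  s
}

# straight axis-aligned vessel from a body center to a frame edge
edgeVessel <- function(center, dir, width, n, attachedTo) {
  r0 <- parityCoord(center[1], width)
  c0 <- parityCoord(center[2], width)
  path <- switch(dir,
    up = rbind(c(r0, c0), c(1, c0)),
    down = rbind(c(r0, c0), c(n, c0)),
    left = rbind(c(r0, c0), c(r0, 1)),
    right = rbind(c(r0, c0), c(r0, n))
  )
  list(path = path, width = width, attachedTo = attachedTo)
}

#' Generate a diverse, seeded set of phantom bundles
#'
#' Draws `nImages` phantom specs from the given parameter ranges (shapes,
#' body diameters, vessel widths, distractor counts) and renders each.
#' Deterministic under `seed`: the same call yields bit-identical bundles.
#'
#' @param nImages number of phantoms (>= 1).
#' @param seed integer master seed.
#' @param specRanges named list overriding any of the default ranges
#'   (`frameSize`, `nFrames`, `bodyDiameter`, `vesselWidth`, `nBodies`,
#'   `nDistractors`, `shapes`, `flickerAmplitude`, `backgroundNoiseSigma`,
#'   `intensityRange`).
#' @return A list of [PhantomBundle-class] objects.
#' @export
makeFixtureSet <- function(nImages, seed = 1L, specRanges = list()) {
  if (nImages < 1) stop("nImages must be >= 1")
  rg <- defaultSpecRanges()
  for (nm in names(specRanges)) rg[[nm]] <- specRanges[[nm]]
  for (nm in c("bodyDiameter", "vesselWidth", "nBodies", "nDistractors", "shapes")) {
    if (length(rg[[nm]]) == 0) stop("empty parameter range: ", nm)
  }
  n <- rg$frameSize
  lapply(seq_len(nImages), function(i) {
    spec <- withSeed(deriveSeed(seed, paste0("phantom-spec-", i)), {
      nb <- if (length(rg$nBodies) == 1) rg$nBodies else sample(rg$nBodies, 1)
      bodies <- list()
      vessels <- list()
      for (b in seq_len(nb)) {
        shape <- if (length(rg$shapes) == 1) rg$shapes else sample(rg$shapes, 1)
        # keep the body (and its placement margin) inside the frame
        diams <- evenSeq(rg$bodyDiameter)
        fits <- vapply(diams, function(dd) {
          boundingRadius(list(diameter = dd, shape = shape)) + 5 < n / 2
        }, logical(1))
        if (!any(fits)) stop("frameSize too small for the bodyDiameter range")
        diams <- diams[fits]
        diam <- if (length(diams) == 1) diams else sample(diams, 1)
        margin <- boundingRadius(list(diameter = diam, shape = shape)) + 4
        placed <- FALSE
        for (try in 1:200) {
          ctr <- runif(2, margin + 1, n - margin)
          ok <- TRUE
          for (prev in bodies) {
            need <- boundingRadius(prev) +
              boundingRadius(list(diameter = diam, shape = shape)) + 4
            if (sqrt(sum((prev$center - ctr)^2)) < need) ok <- FALSE
          }
          if (ok) {
            placed <- TRUE
            break
          }
        }
        if (!placed) next
        ctr <- c(parityCoord(ctr[1], diam), parityCoord(ctr[2], diam))
        bodies[[length(bodies) + 1]] <- list(center = ctr, diameter = diam, shape = shape)
        width <- sample(evenSeq(rg$vesselWidth), 1)
        width <- min(width, diam - 2) # attached vessels stay thinner than the body
        dirs <- sample(c("up", "down", "left", "right"), 2)
        bi <- length(bodies)
        vessels[[length(vessels) + 1]] <- edgeVessel(ctr, dirs[1], width, n, bi)
        vessels[[length(vessels) + 1]] <- edgeVessel(ctr, dirs[2], width, n, bi)
      }
      nd <- if (length(rg$nDistractors) == 1) rg$nDistractors else sample(rg$nDistractors, 1)
      for (d in seq_len(nd)) {
        w <- sample(evenSeq(rg$vesselWidth), 1)
        pos <- runif(1, n * 0.1, n * 0.9)
        if (runif(1) < 0.5) {
          vessels[[length(vessels) + 1]] <- list(
            path = rbind(c(parityCoord(pos, w), 1), c(parityCoord(pos, w), n)),
            width = w, attachedTo = NA
          )
        } else {
          vessels[[length(vessels) + 1]] <- list(
            path = rbind(c(1, parityCoord(pos, w)), c(n, parityCoord(pos, w))),
            width = w, attachedTo = NA
          )
        }
      }
      phantomSpec(
        frameSize = n, nFrames = rg$nFrames, maBodies = bodies,
        vessels = vessels, flickerAmplitude = rg$flickerAmplitude,
        backgroundNoiseSigma = rg$backgroundNoiseSigma,
        intensityRange = rg$intensityRange,
        seed = deriveSeed(seed, paste0("phantom-video-", i))
      )
    })
    generatePhantom(spec)
  })
}

#' Write a phantom bundle to disk
#'
#' Video as multi-page float TIFF, mask as PGM (0/255), truth as a JSON
#' sidecar.
#'
#' @param bundle a [PhantomBundle-class].
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return Named character vector of the three paths, invisibly.
#' @export
writePhantomBundle <- function(bundle, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, paste0(name, "_video.tif"))
  mp <- file.path(dir, paste0(name, "_mask.pgm"))
  tp <- file.path(dir, paste0(name, "_truth.json"))
  writeVideoTIFF(bundle@video, vp)
  writeMaskPGM(bundle@mask, mp)
  jsonlite::write_json(bundle@truth, tp, dataframe = "rows", digits = NA)
  invisible(c(video = vp, mask = mp, truth = tp))
}
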