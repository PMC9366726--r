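# Medial-axis morphometry of segmented MAs. The skeleton of each
# 8-connected component is computed by thinning (with short spurs pruned),
# and the exact Euclidean distance transform supplies the medial radius at
# every skeleton point: the distance to the nearest background pixel center.
# From the sorted radius list D: LC = 2 * max(D) (the body diameter),
# NC = 2 * mean of the 10 smallest radii (the neck/vessel width), and
# BNR = LC / NC.

# remove skeleton branches shorter than pruneLen px that end at a junction;
# repeated until stable so secondary spurs are cleaned too
pruneSpurs <- function(skel, pruneLen) {
  if (pruneLen < 1) {
    return(skel)
  }
  H <- nrow(skel)
  W <- ncol(skel)
  neighOffsets <- cbind(
    rep(-1:1, times = 3), rep(-1:1, each = 3)
  )[-5, , drop = FALSE]
  repeat {
    pts <- which(skel == 1, arr.ind = TRUE)
    if (nrow(pts) == 0) break
    deg <- function(r, c) {
      nr <- r + neighOffsets[, 1]
      nc <- c + neighOffsets[, 2]
      ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
      sum(skel[cbind(nr[ok], nc[ok])])
    }
    degrees <- vapply(seq_len(nrow(pts)), function(i) deg(pts[i, 1], pts[i, 2]), numeric(1))
    ends <- pts[degrees <= 1, , drop = FALSE]
    removedAny <- FALSE
    for (e in seq_len(nrow(ends))) {
      r <- ends[e, 1]
      c <- ends[e, 2]
      if (skel[r, c] == 0) next
      branch <- list(c(r, c))
      prev <- c(NA, NA)
      hitJunction <- FALSE
      while (length(branch) <= pruneLen) {
        nr <- r + neighOffsets[, 1]
        nc <- c + neighOffsets[, 2]
        ok <- nr >= 1 & nr <= H & nc >= 1 & nc <= W
        nb <- cbind(nr[ok], nc[ok])
        nb <- nb[skel[nb] == 1, , drop = FALSE]
        if (!is.na(prev[1])) {
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        }
        if (nrow(nb) == 0) break # isolated path: keep it
        if (nrow(nb) > 1 || deg(nb[1, 1], nb[1, 2]) > 2) {
          hitJunction <- TRUE
          break
        }
        prev <- c(r, c)
        r <- nb[1, 1]
        c <- nb[1, 2]
        branch[[length(branch) + 1]] <- c(r, c)
      }
      if (hitJunction && length(branch) <= pruneLen) {
        for (p in branch) skel[p[1], p[2]] <- 0
        removedAny <- TRUE
      }
    }
    if (!removedAny) break
  }
  skel
}

#' Medial profile of a segmented object
#'
#' Thins the mask to its skeleton (medial axis), prunes boundary spurs
#' shorter than `pruneLen`, and attaches to every skeleton point its medial
#' radius: the exact Euclidean distance to the nearest background pixel
#' center. Points whose medial disk would cross the image frame (object
#' clipped by the crop) are flagged as border-contaminated rather than
#' silently used.
#'
#' If the mask has several 8-connected components the largest is profiled;
#' use [morphometry()] for a per-component report.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param pruneLen spur branches shorter than this many px are removed.
#' @return A [MedialProfile-class].
#' @export
medialProfile <- function(mask, pruneLen = 3L) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@image
  if (sum(m) == 0) stop("empty mask has no medial profile")
  im <- m
  storage.mode(im) <- "integer"
  lab <- cpp_label_components(im)
  if (max(lab) > 1) {
    areas <- tabulate(lab[lab > 0])
    im <- matrix(as.integer(lab == which.max(areas)), nrow(m), ncol(m))
  }
  skel <- cpp_thin(im)
  skel <- pruneSpurs(skel, pruneLen)
  pts <- which(skel == 1, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("skeleton empty after spur pruning")
  edt <- sqrt(cpp_edt_sq(im))
  d <- edt[pts]
  if (any(!is.finite(d))) stop("mask has no background pixels")
  H <- nrow(m)
  W <- ncol(m)
  borderDist <- pmin(pts[, 1], H + 1 - pts[, 1], pts[, 2], W + 1 - pts[, 2])
  new("MedialProfile",
    points = pts, distances = as.numeric(d),
    borderFlag = as.logical(borderDist < d)
  )
}

profileRadii <- function(profile, excludeBorder) {
  d <- profile@distances
  if (excludeBorder && any(!profile@borderFlag)) d <- d[!profile@borderFlag]
  d
}

#' Largest caliber (LC)
#'
#' Twice the largest medial radius in the sorted distance list: the diameter
#' of the largest inscribed disk, a proxy for the MA body diameter.
#'
#' @param profile a [MedialProfile-class].
#' @param excludeBorder drop border-contaminated radii (unless all are).
#' @return LC in px.
#' @export
largestCaliber <- function(profile, excludeBorder = TRUE) {
  2 * max(profileRadii(profile, excludeBorder))
}

#' Narrowest caliber (NC)
#'
#' Twice the mean of the `k` (default 10) smallest medial radii: on a
#' correct segmentation these lie on the feeding/draining vessels, so NC
#' proxies the parent-vessel (neck) width. Profiles with fewer than `k`
#' points use all of them; ties are resolved by stable ascending sort.
#'
#' @param profile a [MedialProfile-class].
#' @param k number of smallest radii averaged.
#' @param excludeBorder drop border-contaminated radii (unless all are).
#' @return NC in px.
#' @export
narrowestCaliber <- function(profile, k = 10L, excludeBorder = TRUE) {
  d <- sort(profileRadii(profile, excludeBorder))
  2 * mean(d[seq_len(min(k, length(d)))])
}

#' Body-to-neck ratio (BNR)
#'
#' `BNR = LC / NC`; larger values mark saccular MAs with narrow necks,
#' associated with rupture/thrombosis propensity.
#'
#' @param lc largest caliber (px).
#' @param nc narrowest caliber (px), > 0.
#' @return Dimensionless ratio.
#' @export
bodyToNeckRatio <- function(lc, nc) {
  if (nc <= 0) stop("NC must be positive")
  lc / nc
}

#' Per-component morphometry report
#'
#' Computes LC, NC and BNR for every 8-connected component of a mask
#' (clinical images may contain several MAs). Distances are float pixels;
#' micron values are added when `umPerPx` is supplied.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param k number of smallest radii in NC.
#' @param pruneLen spur-pruning length for the skeleton.
#' @param umPerPx optional microns per pixel (AOSLO resolves ~2.5 um).
#' @param minArea components below this area (px) are skipped as fragments.
#' @return A [MorphometryReport-class].
#' @export
morphometry <- function(mask, k = 10L, pruneLen = 3L, umPerPx = NA_real_,
                        minArea = 1) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@image
  if (sum(m) == 0) stop("empty mask has no morphometry")
  im <- m
  storage.mode(im) <- "integer"
  lab <- cpp_label_components(im)
  ncomp <- max(lab)
  rows <- list()
  profiles <- list()
  for (ci in seq_len(ncomp)) {
    comp <- matrix(as.numeric(lab == ci), nrow(m), ncol(m))
    area <- sum(comp)
    if (area < minArea) next
    prof <- medialProfile(binaryMask(comp), pruneLen = pruneLen)
    lc <- largestCaliber(prof)
    nc <- narrowestCaliber(prof, k = k)
    rows[[length(rows) + 1]] <- data.frame(
      component = ci, area = area, lc = lc, nc = nc,
      bnr = bodyToNeckRatio(lc, nc),
      nSkeleton = length(prof@distances),
      nBorderFlagged = sum(prof@borderFlag)
    )
    profiles[[length(profiles) + 1]] <- prof
  }
  if (length(rows) == 0) stop("no component reaches minArea")
  comp <- do.call(rbind, rows)
  if (!is.na(umPerPx)) {
    comp$lcUm <- comp$lc * umPerPx
    comp$ncUm <- comp$nc * umPerPx
  }
  new("MorphometryReport",
    components = comp, profiles = profiles,
    umPerPx = as.numeric(umPerPx)
  )
}
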