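# Minimal baseline TIFF and binary PGM I/O.
#
# The package writes uncompressed little-endian TIFF (32-bit float, one page
# per video frame, single strip per page) and reads back the baseline subset
# it writes plus unsigned 8/16-bit grayscale. Masks travel as binary PGM
# (P5, 0/255). Both formats are implemented directly over readBin/writeBin
# because no image I/O package is available in the target library.

tiffEntry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3) { # SHORT: value left-justified in the 4-byte field
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

writeTiffPages <- function(mats, path) {
  H <- nrow(mats[[1]])
  W <- ncol(mats[[1]])
  P <- length(mats)
  bytesPerPage <- H * W * 4
  dataStart <- 8
  firstIFD <- dataStart + P * bytesPerPage
  ifdSize <- 2 + 10 * 12 + 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(firstIFD), con, size = 4, endian = "little")
  for (m in mats) { # strips are row-major
    writeBin(as.numeric(as.vector(t(m))), con, size = 4, endian = "little")
  }
  for (p in seq_len(P)) {
    writeBin(10L, con, size = 2, endian = "little")
    tiffEntry(con, 256, 4, 1, W)
    tiffEntry(con, 257, 4, 1, H)
    tiffEntry(con, 258, 3, 1, 32)
    tiffEntry(con, 259, 3, 1, 1) # no compression
    tiffEntry(con, 262, 3, 1, 1) # BlackIsZero
    tiffEntry(con, 273, 4, 1, dataStart + (p - 1) * bytesPerPage)
    tiffEntry(con, 277, 3, 1, 1)
    tiffEntry(con, 278, 4, 1, H)
    tiffEntry(con, 279, 4, 1, bytesPerPage)
    tiffEntry(con, 339, 3, 1, 3) # IEEE float samples
    nextIFD <- if (p < P) firstIFD + p * ifdSize else 0L
    writeBin(as.integer(nextIFD), con, size = 4, endian = "little")
  }
  invisible(path)
}

readTiffPages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  byteOrder <- readChar(con, 2)
  endian <- if (byteOrder == "II") "little" else if (byteOrder == "MM") "big" else {
    stop("not a TIFF file: ", path)
  }
  magic <- readBin(con, "integer", size = 2, endian = endian)
  if (magic != 42) stop("not a TIFF file: ", path)
  ifdOffset <- readBin(con, "integer", size = 4, endian = endian)
  pages <- list()
  readValues <- function(type, count, raw) {
    size <- c(`1` = 1, `3` = 2, `4` = 4)[[as.character(type)]]
    vcon <- rawConnection(raw)
    on.exit(close(vcon))
    if (size * count <= 4) {
      readBin(vcon, "integer", n = count, size = size, endian = endian,
        signed = size > 2)
    } else {
      off <- readBin(vcon, "integer", size = 4, endian = endian)
      cur <- seek(con)
      seek(con, off)
      v <- readBin(con, "integer", n = count, size = size, endian = endian,
        signed = size > 2)
      seek(con, cur)
      v
    }
  }
  while (ifdOffset != 0) {
    seek(con, ifdOffset)
    nEntries <- readBin(con, "integer", size = 2, endian = endian)
    tags <- list()
    for (i in seq_len(nEntries)) {
      tag <- readBin(con, "integer", size = 2, endian = endian)
      type <- readBin(con, "integer", size = 2, endian = endian)
      count <- readBin(con, "integer", size = 4, endian = endian)
      raw <- readBin(con, "raw", n = 4)
      if (tag %in% c(256, 257, 258, 259, 273, 277, 278, 279, 339)) {
        tags[[as.character(tag)]] <- readValues(type, count, raw)
      }
    }
    ifdOffset <- readBin(con, "integer", size = 4, endian = endian)
    W <- tags[["256"]]
    H <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 8 else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
    if (comp != 1) stop("only uncompressed TIFF is supported")
    offs <- tags[["273"]]
    counts <- tags[["279"]]
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      if (fmt == 3 && bits == 32) {
        vals <- c(vals, readBin(con, "double", n = counts[s] / 4, size = 4,
          endian = endian))
      } else if (bits == 16) {
        vals <- c(vals, readBin(con, "integer", n = counts[s] / 2, size = 2,
          endian = endian, signed = FALSE) / 65535)
      } else if (bits == 8) {
        vals <- c(vals, as.integer(readBin(con, "raw", n = counts[s])) / 255)
      } else {
        stop("unsupported TIFF sample layout (", bits, " bits, format ", fmt, ")")
      }
    }
    pages[[length(pages) + 1]] <- t(matrix(vals, nrow = W, ncol = H))
  }
  pages
}

#' Write a video stack as a multi-page TIFF
#'
#' One 32-bit float page per frame, uncompressed, little-endian.
#'
#' @param video a [VideoStack-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeVideoTIFF <- function(video, path) {
  stopifnot(is(video, "VideoStack"))
  f <- video@frames
  writeTiffPages(lapply(seq_len(dim(f)[3]), function(i) f[, , i]), path)
}

#' Read a multi-page TIFF as a video stack
#'
#' Supports the uncompressed grayscale subset written by [writeVideoTIFF()]
#' plus unsigned 8/16-bit pages (rescaled to `[0, 1]`).
#'
#' @param path TIFF file path.
#' @return A [VideoStack-class].
#' @export
readVideoTIFF <- function(path) {
  pages <- readTiffPages(path)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) a[, , i] <- pages[[i]]
  videoStack(clamp(a, 0, 1))
}

#' Write a single image matrix as a float TIFF
#' @param image numeric matrix (or an image S4 object with one channel).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeImageTIFF <- function(image, path) {
  if (!is.matrix(image)) image <- imageData(image)
  writeTiffPages(list(image), path)
}

#' Read a single-page TIFF as a matrix
#' @param path TIFF file path.
#' @return A numeric matrix.
#' @export
readImageTIFF <- function(path) readTiffPages(path)[[1]]

#' Write a two-channel image as a 2-page float TIFF
#' @param image a [TwoChannelImage-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeTwoChannelTIFF <- function(image, path) {
  stopifnot(is(image, "TwoChannelImage"))
  writeTiffPages(list(image@enhanced, image@perfusion), path)
}

#' Read a 2-page float TIFF as a two-channel image
#' @param path TIFF file path.
#' @return A [TwoChannelImage-class].
#' @export
readTwoChannelTIFF <- function(path) {
  pages <- readTiffPages(path)
  if (length(pages) != 2) stop("expected a 2-page TIFF, got ", length(pages))
  twoChannelImage(pages[[1]], pages[[2]])
}

#' Write a binary mask as PGM (P5, 0/255)
#' @param mask a [BinaryMask-class] or 0/1 matrix.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeMaskPGM <- function(mask, path) {
  m <- if (is(mask, "BinaryMask")) mask@image else mask
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.raw(as.vector(t(m)) * 255), con)
  invisible(path)
}

#' Read a binary PGM as a mask
#' @param path PGM (P5) file path.
#' @return A [BinaryMask-class]; pixels above 127 map to 1.
#' @export
readMaskPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PGM header")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- readToken()
  if (magic != "P5") stop("only binary PGM (P5) is supported")
  W <- as.integer(readToken())
  H <- as.integer(readToken())
  maxval <- as.integer(readToken())
  v <- as.integer(readBin(con, "raw", n = W * H))
  binaryMask(t(matrix(as.numeric(v > maxval / 2), nrow = W, ncol = H)))
}
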