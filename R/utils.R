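#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-stream seed from a global seed
#'
#' Deterministically maps a (seed, stage name) pair to a new 31-bit seed, so
#' pipeline stages draw from independent named streams that all flow from one
#' global seed.
#'
#' @param seed integer global seed.
#' @param tag character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483646) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isOdd <- function(x) x %% 2 == 1

stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
}
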