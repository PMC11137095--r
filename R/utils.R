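# Internal helpers: seeded RNG scoping, deterministic sub-seeds, block downsampling.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  force(code)
}

#' Mix integers into a deterministic sub-seed below 2^31
#'
#' Used to give each (patch, slide) its own reproducible stream independent of
#' evaluation order. Plain multiplicative hash over a Mersenne-ish modulus.
#' @noRd
subseed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1)))
  h <- 0
  m <- 2147483647 # 2^31 - 1
  for (p in parts) {
    h <- ((h * 48271) %% m + (abs(p) %% m) + 1) %% m
  }
  as.integer(h)
}

#' Block-mean downsample a 2-D matrix or H x W x C array by an integer factor
#'
#' Trailing rows/columns that do not fill a complete block are dropped, so the
#' output dimensions are floor(dim / factor).
#' @noRd
block_downsample <- function(x, factor = 2L) {
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  if (length(dim(x)) == 2L) {
    h <- nrow(x) %/% factor
    w <- ncol(x) %/% factor
    x <- x[seq_len(h * factor), seq_len(w * factor), drop = FALSE]
    # column-major reshape exposes the block axes; two colMeans reductions
    y <- array(x, dim = c(factor, h, factor, w))
    z <- colMeans(y, dims = 1)              # (h, factor, w)
    out <- colMeans(aperm(z, c(2, 1, 3)), dims = 1)
    dim(out) <- c(h, w)
    return(out)
  }
  stopifnot(length(dim(x)) == 3L)
  ch <- dim(x)[3]
  h <- dim(x)[1] %/% factor
  w <- dim(x)[2] %/% factor
  out <- array(0, dim = c(h, w, ch))
  for (k in seq_len(ch)) out[, , k] <- block_downsample(x[, , k], factor)
  out
}

#' Clamp a numeric object into [lo, hi]
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Flatten an H x W x 3 raster into an N x 3 matrix of pixels (row-major over
# the array's internal column order; the inverse reshape restores it exactly).
flatten_px <- function(raster) {
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 3L)
  matrix(raster, ncol = 3L)
}

unflatten_px <- function(px, dims) {
  array(px, dim = dims)
}
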