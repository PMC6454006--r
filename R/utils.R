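#' @include AllClasses.R
NULL

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so identical inputs give
# bit-identical outputs and no global state leaks.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Round a score the way challenge tables print it
#'
#' Scores are printed at three decimals with ties rounded half-up (so the mean
#' of 0.702 and 0.849, namely 0.7755, prints as 0.776). Base \code{round()}
#' rounds half to even and would print 0.775.
#'
#' @param x numeric score(s).
#' @param digits decimal places (default 3).
#' @return rounded numeric.
#' @export
printedScore <- function(x, digits = 3) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Per-cell argmax over the three class maps; 1 = ND, 2 = LUAD, 3 = LUSC.
# Ties resolve to the first (lowest) class index, matching max.col "first".
argmaxMaps <- function(maps) {
  m <- cbind(as.vector(maps@nd), as.vector(maps@luad), as.vector(maps@lusc))
  am <- max.col(m, ties.method = "first")
  matrix(am, nrow = nrow(maps@nd))
}

# Reflection-pad an (H, W, C) array or a matrix by `pad` pixels on every side.
reflectPad <- function(x, pad) {
  mirror <- function(idx, n) {
    idx <- ((idx) %% (2L * n))
    idx[idx < 0L] <- idx[idx < 0L] + 2L * n
    ifelse(idx < n, idx, 2L * n - 1L - idx)
  }
  ism <- is.matrix(x)
  d <- if (ism) c(dim(x), 1L) else dim(x)
  ri <- mirror(seq.int(-pad, d[1] + pad - 1L), d[1]) + 1L
  ci <- mirror(seq.int(-pad, d[2] + pad - 1L), d[2]) + 1L
  out <- if (ism) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  out
}

# 3x3 box dilation of a binary mask (logical or 0/1 matrix), `iter` times.
dilateBox3 <- function(mask, iter = 1L) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (iter >= 1L) {
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(iter)) m <- EBImage::dilate(m, brush)
  }
  m > 0
}

stopifnotScalarIn01 <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]")
}
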