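#' @importFrom stats approx var sd cor rnorm runif optim quantile aggregate
#' @importFrom utils head tail write.csv read.csv
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic operations in the package go through this so that a `seed`
# argument makes them reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Linear resampling of a vector to n_out samples over the same support.
resample_linear <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  if (n == 1L) return(rep(x, n_out))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y
}

# Fill NA runs by linear interpolation, extending flat at the edges.
fill_na_linear <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(rep(0, length(x)))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
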