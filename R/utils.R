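# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Run code with a temporarily seeded RNG
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's
#' `.Random.seed` so internal randomness (e.g. correlation-dimension
#' subsampling) never perturbs user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive per-task child seeds (< 2^31) from a master seed, reproducibly
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# 3D summed-area table; S[i+1,j+1,k+1] = sum of x[1:i,1:j,1:k]
cumsum3d <- function(x) {
  d <- dim(x)
  s <- array(0, d + 1L)
  s[-1L, -1L, -1L] <- x
  s <- apply(s, c(2L, 3L), cumsum)
  dim(s) <- d + 1L
  s <- aperm(apply(s, c(1L, 3L), cumsum), c(2L, 1L, 3L))
  s <- aperm(apply(s, c(1L, 2L), cumsum), c(2L, 3L, 1L))
  s
}

# sum of x over every k^3 window; returns array of window sums
window_sums <- function(x, k) {
  s <- cumsum3d(x)
  d <- dim(x)
  n <- d - k + 1L
  i <- seq_len(n[1]); j <- seq_len(n[2]); l <- seq_len(n[3])
  s[i + k, j + k, l + k, drop = FALSE] -
    s[i,     j + k, l + k, drop = FALSE] -
    s[i + k, j,     l + k, drop = FALSE] -
    s[i + k, j + k, l,     drop = FALSE] +
    s[i + k, j,     l,     drop = FALSE] +
    s[i,     j + k, l,     drop = FALSE] +
    s[i,     j,     l + k, drop = FALSE] -
    s[i,     j,     l,     drop = FALSE]
}
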