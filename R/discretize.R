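#' Gray-level discretization of a voxel grid
#'
#' Two schemes are provided, matching the two discretizations used throughout
#' the feature set: equal-size bins (`es`, fixed bin width over the observed
#' intensity range) and equal-probability bins (`ep`, empirical quantiles so
#' levels hold equally many voxels). The default level count is 128; both
#' scheme tag and level count appear in downstream feature names (`es_128`,
#' `ep_128`).
#'
#' Bins are computed over all voxels of the exported box (the pipeline uses
#' no segmentation mask). Constant images are legal and occupy level 1 only.
#'
#' @param grid a [voxel_grid()].
#' @param L number of gray levels, >= 2 (default 128).
#' @return An object of class `discretized_image`: list with `levels`
#'   (integer 3D array in 1..L), `L`, `scheme`, `bin_edges` (length L+1,
#'   non-decreasing, SUV units), `spacing`, `source_id`.
#' @name discretize
NULL

new_discretized <- function(levels, L, scheme, edges, grid) {
  structure(list(levels = levels, L = as.integer(L), scheme = scheme,
                 bin_edges = edges, spacing = grid$spacing,
                 source_id = grid$case_id),
            class = "discretized_image")
}

#' @rdname discretize
#' @export
discretize_es <- function(grid, L = 128L) {
  L <- as.integer(L)
  if (L < 2L) stopf("L must be >= 2")
  x <- grid$values
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    lev <- array(1L, dim(x))
    edges <- rep(lo, L + 1L)
  } else {
    w <- (hi - lo) / L
    lev <- pmin.int(as.integer(floor((x - lo) / w)) + 1L, L)
    dim(lev) <- dim(x)
    edges <- lo + w * (0:L)
  }
  new_discretized(lev, L, "es", edges, grid)
}

#' @rdname discretize
#' @details For `ep`, a repeated value is always assigned entirely to one
#'   level (ties never straddle a level edge): the level of a value is
#'   determined by the position of its first occurrence in the sorted sample,
#'   `floor((pos - 1) * L / N) + 1`. With N distinct values the level
#'   populations differ by at most 1.
#' @export
discretize_ep <- function(grid, L = 128L) {
  L <- as.integer(L)
  if (L < 2L) stopf("L must be >= 2")
  x <- grid$values
  n <- length(x)
  r <- rle(sort(as.vector(x)))          # exact doubles, no name round-trip
  u <- r$values
  first_pos <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  lev_u <- pmin.int(as.integer(floor((first_pos - 1) * L / n)) + 1L, L)
  lev <- lev_u[findInterval(x, u)]
  dim(lev) <- dim(x)
  # edge k+1 = smallest value mapped to a level > k (carry forward when empty)
  edges <- numeric(L + 1L)
  edges[1L] <- u[1L]
  for (k in seq_len(L - 1L)) {
    nxt <- u[lev_u > k]
    edges[k + 1L] <- if (length(nxt)) nxt[1L] else edges[k]
  }
  edges[L + 1L] <- u[length(u)]
  edges <- cummax(edges)
  new_discretized(lev, L, "ep", edges, grid)
}

#' @export
print.discretized_image <- function(x, ...) {
  cat(sprintf("<discretized_image '%s'> %s, L = %d (%s), %d occupied level(s)\n",
              x$source_id, paste(dim(x$levels), collapse = "x"), x$L,
              x$scheme, length(unique(as.vector(x$levels)))))
  invisible(x)
}
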