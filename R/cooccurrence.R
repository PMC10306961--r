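#' 3D gray-level co-occurrence and run-length texture
#'
#' Co-occurrence (GLCM) and run-length (GLRLM) matrices are built for the 13
#' unique 3D lattice directions at a given Chebyshev distance (default 1),
#' symmetrized, and aggregated by the arithmetic mean — the `d1_mean`
#' convention in the feature-name grammar.
#'
#' @name cooccurrence
NULL

# the 13 unique 3D offsets at Chebyshev distance 1 (opposites excluded)
unique_directions <- function() {
  list(c(1,0,0), c(0,1,0), c(0,0,1),
       c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
       c(1,1,1), c(1,1,-1), c(1,-1,1), c(-1,1,1))
}

# index ranges of the valid voxel pairs for an offset; NULL when no pairs
offset_ranges <- function(d, off) {
  rng <- vector("list", 3L)
  for (a in 1:3) {
    lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(NULL)
    rng[[a]] <- seq.int(lo, hi)
  }
  rng
}

#' Build one GLCM per unique 3D direction
#'
#' Counts co-occurring gray-level pairs at the given voxel offset, adds the
#' transpose (symmetrization) and normalizes to total mass 1. Directions with
#' no valid voxel pair (image thinner than the offset) are dropped; if no
#' direction yields a pair the call errors.
#'
#' @param disc a `discretized_image`.
#' @param distance positive integer Chebyshev distance (offsets scaled by it).
#' @return List of `glcm` objects (fields `matrix`, `direction`, `distance`,
#'   `L`, `symmetric`).
#' @export
build_glcms <- function(disc, distance = 1L) {
  distance <- as.integer(distance)
  if (distance < 1L) stopf("distance must be >= 1")
  lev <- disc$levels; L <- disc$L; d <- dim(lev)
  out <- list()
  for (dir in unique_directions()) {
    off <- dir * distance
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    a <- lev[rng[[1]], rng[[2]], rng[[3]]]
    b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3]]
    cnt <- tabulate((a - 1L) * L + b, nbins = L * L)
    m <- matrix(cnt, L, L, byrow = TRUE)      # row = level of a, col = level of b
    m <- m + t(m)
    out[[length(out) + 1L]] <- structure(
      list(matrix = m / sum(m), direction = dir, distance = distance,
           L = L, symmetric = TRUE),
      class = "glcm")
  }
  if (!length(out))
    stopf("image has no voxel pair at distance %d in any direction", distance)
  out
}

#' Entrywise mean of a list of GLCMs
#'
#' @param glcms non-empty list of `glcm` objects with equal level count.
#' @return A single `glcm` whose matrix is the arithmetic mean (still sums
#'   to 1); direction is `NA` (aggregate).
#' @export
aggregate_mean <- function(glcms) {
  if (!length(glcms)) stopf("empty GLCM list")
  Ls <- vapply(glcms, function(g) g$L, integer(1))
  if (length(unique(Ls)) != 1L) stopf("GLCMs have differing level counts")
  m <- Reduce(`+`, lapply(glcms, function(g) g$matrix)) / length(glcms)
  structure(list(matrix = m, direction = NA, distance = glcms[[1]]$distance,
                 L = Ls[1], symmetric = all(vapply(glcms, function(g)
                   isTRUE(g$symmetric), logical(1)))),
            class = "glcm")
}

glcm_stat_names <- c("Contrast_s", "Homogeneity_s", "Homogeneity2_e",
                     "Cluster_p_s", "Cluster_sh_s", "Cluster_d_s",
                     "Inv_Gauss_2p_s", "Inv_Gauss_2f_s")

glcm_stats_core <- function(p, L) {
  I <- row(p); J <- col(p)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(pi_ * seq_len(L)); mu_j <- sum(pj_ * seq_len(L))
  dev <- I + J - mu_i - mu_j
  star <- which.max(p)                       # ties: first in column-major order
  istar <- (star - 1L) %% L + 1L
  jstar <- (star - 1L) %/% L + 1L
  c(sum(p * (I - J)^2),
    sum(p / (1 + abs(I - J))),
    sum(p / (1 + (I - J)^2)),
    sum(p * dev^4),
    sum(p * dev^3),
    sum(p * abs(I - J)),
    sum(p * exp(-((I - J) / L)^2)),
    sum(p * exp(-((I - istar)^2 + (J - jstar)^2) / L^2)))
}

#' GLCM statistics
#'
#' With `p(i,j)` the normalized matrix and marginal means
#' `mu_i = sum(i * p_i(i))`, `mu_j` likewise:
#' contrast `sum p (i-j)^2`; homogeneity `sum p / (1+|i-j|)`;
#' homogeneity-squared `sum p / (1+(i-j)^2)`; cluster prominence / shade
#' `sum p (i+j-mu_i-mu_j)^{4,3}`; cluster difference (dissimilarity)
#' `sum p |i-j|`; inverse Gaussian 2 polar `sum p exp(-((i-j)/L)^2)`
#' (distance from the diagonal); inverse Gaussian 2 focus
#' `sum p exp(-((i-i*)^2+(j-j*)^2)/L^2)` with `(i*,j*)` the matrix's maximal
#' cell. Every statistic is also emitted in a non-diagonal (`_nd`) variant:
#' diagonal cells removed, matrix renormalized (missing when all mass is
#' diagonal).
#'
#' @param glcm a normalized `glcm`.
#' @param suffix appended to each statistic token to form the feature id,
#'   e.g. `"__es_b128_d1_mean"`; empty for bare names.
#' @return Named numeric vector of 16 statistics (8 plain + 8 `_nd`).
#' @export
glcm_statistics <- function(glcm, suffix = "") {
  p <- glcm$matrix; L <- glcm$L
  if (abs(sum(p) - 1) > 1e-8) stopf("GLCM is not normalized")
  plain <- glcm_stats_core(p, L)
  pnd <- p; diag(pnd) <- 0
  snd <- sum(pnd)
  nd <- if (snd > 0) glcm_stats_core(pnd / snd, L) else rep(NA_real_, length(plain))
  stats::setNames(c(plain, nd),
                  paste0(c(glcm_stat_names, paste0(glcm_stat_names, "_nd")),
                         suffix))
}

#' Build a gray-level run-length matrix for one direction
#'
#' Counts maximal runs of identical gray level along every lattice line
#' parallel to `direction`; entry `(g, r)` is the number of maximal runs of
#' level `g` with length `r`. Each voxel belongs to exactly one maximal run,
#' so `sum_g sum_r r * count(g, r)` equals the voxel count.
#'
#' @param disc a `discretized_image`.
#' @param direction nonzero integer offset triple with components in -1..1.
#' @return A `glrlm` object (fields `matrix` (L x Rmax counts), `direction`).
#' @export
build_glrlm <- function(disc, direction) {
  direction <- as.integer(direction)
  if (all(direction == 0L)) stopf("direction must be nonzero")
  lev <- disc$levels; d <- dim(lev); L <- disc$L
  idx <- arrayInd(seq_along(lev), d)
  # parameter along the line: coordinate of the first axis the offset moves
  ax <- which(direction != 0L)[1L]
  t_par <- idx[, ax] * direction[ax]          # sign so t increases along 'direction'
  # line key: starting point of the line through each voxel
  base <- idx - outer(t_par, direction)       # constant along a line
  b1 <- base[, 1] - min(base[, 1]); r1 <- max(b1) + 1L
  b2 <- base[, 2] - min(base[, 2]); r2 <- max(b2) + 1L
  key <- b1 + b2 * r1 + (base[, 3] - min(base[, 3])) * r1 * r2
  ord <- order(key, t_par)
  g <- as.vector(lev)[ord]
  k <- key[ord]
  n <- length(g)
  brk <- c(TRUE, k[-1L] != k[-n] | g[-1L] != g[-n])   # new run starts
  starts <- which(brk)
  lens <- diff(c(starts, n + 1L))
  glev <- g[starts]
  rmax <- max(lens)
  m <- matrix(tabulate((lens - 1L) * L + glev, nbins = L * rmax), L, rmax)
  structure(list(matrix = m, direction = direction, L = L), class = "glrlm")
}

#' GLRLM statistics
#'
#' With `r` the total run count: gray-level non-uniformity
#' `GLN = sum_g (sum_len count)^2 / r`; run-length non-uniformity
#' `RLN = sum_len (sum_g count)^2 / r`; short- and long-run emphasis
#' `SRE = sum count/len^2 / r`, `LRE = sum count*len^2 / r`.
#'
#' @param glrlm a `glrlm` with at least one run.
#' @param suffix appended to each token to form feature ids.
#' @return Named numeric vector `GLN`, `RLN`, `SRE`, `LRE`.
#' @export
glrlm_statistics <- function(glrlm, suffix = "") {
  m <- glrlm$matrix
  r <- sum(m)
  if (r < 1) stopf("empty run-length matrix")
  lens <- seq_len(ncol(m))
  stats::setNames(
    c(sum(rowSums(m)^2) / r,
      sum(colSums(m)^2) / r,
      sum(sweep(m, 2L, lens^2, `/`)) / r,
      sum(sweep(m, 2L, lens^2, `*`)) / r),
    paste0(c("GLN", "RLN", "SRE", "LRE"), suffix))
}

# direction-averaged GLCM + GLRLM feature block for one discretized image
cooccurrence_feature_block <- function(disc, distance = 1L) {
  suffix <- sprintf("__%s_b%d_d%d_mean", disc$scheme, disc$L, distance)
  gl <- glcm_statistics(aggregate_mean(build_glcms(disc, distance)), suffix)
  rl_per_dir <- lapply(unique_directions(), function(dir)
    glrlm_statistics(build_glrlm(disc, dir)))
  rl <- Reduce(`+`, rl_per_dir) / length(rl_per_dir)
  names(rl) <- paste0(c("GLN", "RLN", "SRE", "LRE"), suffix)
  c(gl, rl)
}
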