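#' First-order (histogram) statistics of the SUV distribution
#'
#' Statistics of the voxel-value distribution ignoring spatial arrangement,
#' computed on the original (non-discretized) volume and suffixed `__orig`.
#'
#' Conventions (fixed so every oracle agrees):
#' * median of an even count = mean of the two central order statistics;
#' * mode = center of the modal bin of an equal-size `hist_levels`-bin
#'   histogram (continuous data has no exact mode); ties break to the lowest
#'   bin; a constant image has mode equal to its value;
#' * skewness/kurtosis are the population (biased) moment estimators,
#'   kurtosis reported as excess; both missing for zero-variance input;
#' * standard deviation is the sample (n-1) estimator;
#' * `Energy` is the sum of squared values; `Entropy` is Shannon entropy
#'   (bits) of the equal-size histogram;
#' * `Max_AD_md` is the maximum absolute deviation from the median.
#'
#' @param grid a [voxel_grid()].
#' @param hist_levels bin count for the mode/entropy histogram (default 128,
#'   the pipeline's gray-level count).
#' @return Named numeric vector (a feature vector block), ids `<Stat>__orig`.
#' @export
first_order_features <- function(grid, hist_levels = 128L) {
  x <- as.vector(grid$values)
  n <- length(x)
  if (n < 1L) stopf("empty grid")
  mu <- mean(x)
  md <- stats::median(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else NA_real_
  if (max(x) > min(x)) {
    br <- seq(min(x), max(x), length.out = hist_levels + 1L)
    cnt <- tabulate(pmin.int(findInterval(x, br, rightmost.closed = TRUE),
                             hist_levels), nbins = hist_levels)
    modal <- which.max(cnt)               # which.max ties -> lowest bin
    mode_v <- (br[modal] + br[modal + 1L]) / 2
    p <- cnt[cnt > 0] / n
    entropy <- -sum(p * log2(p))
  } else {
    mode_v <- x[1L]
    entropy <- 0
  }
  c(Mean__orig = mu,
    Median__orig = md,
    Mode__orig = mode_v,
    SD__orig = if (n > 1L) stats::sd(x) else 0,
    Min__orig = min(x),
    Max__orig = max(x),
    Range__orig = max(x) - min(x),
    Skewness__orig = skew,
    Kurtosis__orig = kurt,
    Energy__orig = sum(x^2),
    Entropy__orig = entropy,
    Max_AD_md__orig = max(abs(x - md)))
}

#' Write a feature table (cases x features) as CSV
#'
#' One row per case, one column per feature id, missing values as empty
#' cells. Column order is the registry order of the first row.
#'
#' @param rows named list: case_id -> named numeric feature vector.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  ids <- names(rows[[1L]])
  m <- do.call(rbind, lapply(rows, function(r) r[ids]))
  df <- data.frame(case_id = names(rows), m, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
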