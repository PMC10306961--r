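#' Feature registry and per-case extraction
#'
#' A single frozen registry enumerates every feature id the pipeline may
#' emit for a given configuration — first-order (`__orig`), GLCM + GLRLM
#' (`__<scheme>_b<L>_d<d>_mean`) and geometric/fractal (`__<scheme>_<L>`)
#' blocks. Extraction refuses to emit ids outside the registry, so the
#' filter/model stages and all tests share a stable feature namespace.
#'
#' @param levels gray-level count L (default 128).
#' @param schemes discretization schemes, subset of `c("es", "ep")`.
#' @param distance GLCM/GLRLM Chebyshev distance.
#' @param fractal_levels gray levels swept by the fractal block (default
#'   `1:levels`).
#' @param ref_level reference level of the volume/surface block.
#' @return Character vector of feature ids in canonical order.
#' @export
feature_registry <- function(levels = 128L, schemes = c("es", "ep"),
                             distance = 1L,
                             fractal_levels = seq_len(levels),
                             ref_level = ceiling(levels / 2)) {
  fo <- c("Mean", "Median", "Mode", "SD", "Min", "Max", "Range", "Skewness",
          "Kurtosis", "Energy", "Entropy", "Max_AD_md")
  ids <- paste0(fo, "__orig")
  for (scheme in schemes) {
    co_suffix <- sprintf("__%s_b%d_d%d_mean", scheme, levels, distance)
    ids <- c(ids,
             paste0(c(glcm_stat_names, paste0(glcm_stat_names, "_nd")), co_suffix),
             paste0(c("GLN", "RLN", "SRE", "LRE"), co_suffix))
    geo_suffix <- sprintf("__%s_%d", scheme, levels)
    for (g in fractal_levels)
      ids <- c(ids, sprintf("fractal_%s_d_%d%s", c("bc", "c"), g, geo_suffix))
    ids <- c(ids, sprintf("%s_%d%s", c("Volume", "Surface", "Surf_vol_ratio"),
                          ref_level, geo_suffix))
  }
  ids
}

#' Extract the full radiomic feature vector of one volume
#'
#' Computes the whole image from the exported box, without masks: the
#' first-order block on original values, then per discretization scheme the
#' direction-averaged GLCM/GLRLM statistics and the per-level fractal and
#' volume/surface block. Output names match [feature_registry()] exactly,
#' in order; inestimable features are `NA`.
#'
#' @param grid a [voxel_grid()].
#' @inheritParams feature_registry
#' @param cd_max_points correlation-dimension subsampling cap.
#' @return Named numeric vector.
#' @export
extract_features <- function(grid, levels = 128L, schemes = c("es", "ep"),
                             distance = 1L,
                             fractal_levels = seq_len(levels),
                             ref_level = ceiling(levels / 2),
                             cd_max_points = 2000L) {
  schemes <- match.arg(schemes, c("es", "ep"), several.ok = TRUE)
  out <- first_order_features(grid, hist_levels = levels)
  for (scheme in schemes) {
    disc <- if (scheme == "es") discretize_es(grid, levels)
            else discretize_ep(grid, levels)
    out <- c(out,
             cooccurrence_feature_block(disc, distance),
             geometric_feature_block(disc, levels = fractal_levels,
                                     ref_level = ref_level,
                                     cd_max_points = cd_max_points))
  }
  reg <- feature_registry(levels, schemes, distance, fractal_levels, ref_level)
  extra <- setdiff(names(out), reg)
  if (length(extra))
    stopf("extraction produced ids outside the registry: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  out[reg]
}

#' Extract features for every NIfTI volume in a directory
#'
#' One row per case (file name stem = case id), deterministic column order
#' from the registry. A per-case failure is logged and leaves the row
#' missing rather than aborting the batch.
#'
#' @param input_dir directory of `.nii` / `.nii.gz` files.
#' @param out_csv optional path; when given the table is written as CSV
#'   (missing values as empty cells).
#' @inheritParams extract_features
#' @param verbose print per-case progress.
#' @return Data frame: `case_id` plus one column per registry feature.
#' @export
extract_cohort <- function(input_dir, out_csv = NULL, levels = 128L,
                           schemes = c("es", "ep"), distance = 1L,
                           fractal_levels = seq_len(levels),
                           ref_level = ceiling(levels / 2),
                           cd_max_points = 2000L, verbose = FALSE) {
  files <- sort(list.files(input_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stopf("no NIfTI volumes found in %s", input_dir)
  reg <- feature_registry(levels, schemes, distance, fractal_levels, ref_level)
  rows <- lapply(files, function(f) {
    t0 <- proc.time()[["elapsed"]]
    fv <- tryCatch(extract_features(read_nifti(f), levels, schemes, distance,
                                    fractal_levels, ref_level, cd_max_points),
                   error = function(e) {
                     warning(sprintf("case %s failed: %s", basename(f),
                                     conditionMessage(e)), call. = FALSE)
                     stats::setNames(rep(NA_real_, length(reg)), reg)
                   })
    if (verbose)
      message(sprintf("  %s: %d features, %.1fs", basename(f), length(fv),
                      proc.time()[["elapsed"]] - t0))
    fv
  })
  names(rows) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  df <- data.frame(case_id = names(rows),
                   do.call(rbind, lapply(rows, `[`, reg)),
                   check.names = FALSE, row.names = NULL)
  if (!is.null(out_csv))
    utils::write.csv(df, out_csv, row.names = FALSE, na = "")
  df
}
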