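#' Tumor-to-normal brain uptake ratio (TNR)
#'
#' The malignancy proxy the regression models predict: mean SUV in the
#' hottest 1.0 cm^3 of the tumor (SUVt) divided by mean SUV in a 1.0 cm^3
#' normal-tissue reference region (SUVn), TNR = SUVt / SUVn.
#'
#' @name tnr
NULL

#' Mean SUV of the hottest cubic region of a target volume
#'
#' Exhaustively slides a cubic window whose edge (in voxels) best
#' approximates `target_volume`, using a 3D summed-area table, and returns
#' the maximal window mean and the window's location. A cube rather than a
#' sphere keeps the search exact and exhaustive.
#'
#' @param grid a [voxel_grid()].
#' @param target_volume physical window volume in cm^3 (default 1.0).
#' @return List: `suv_t` (max window mean), `region` (list `corner` 0-based,
#'   `shape`), `volume_mm3` of the realized window.
#' @export
hottest_region_mean <- function(grid, target_volume = 1.0) {
  vv <- voxel_volume(grid)
  k <- max(1L, as.integer(round((target_volume * 1000 / vv)^(1 / 3))))
  d <- dim(grid$values)
  if (any(d < k))
    stopf("grid %s is smaller than the %d-voxel search window",
          paste(d, collapse = "x"), k)
  sums <- window_sums(grid$values, k)
  best <- which.max(sums)
  corner <- arrayInd(best, dim(sums))[1, ] - 1L
  list(suv_t = sums[best] / k^3,
       region = list(corner = as.integer(corner), shape = rep(k, 3L)),
       volume_mm3 = k^3 * vv)
}

#' Mean SUV of a reference (normal-tissue) region
#'
#' @param grid a [voxel_grid()].
#' @param region list with 0-based `corner` and `shape` voxel triples.
#' @return The arithmetic mean over the region; errors when the mean is not
#'   strictly positive (TNR would be undefined).
#' @export
reference_region_mean <- function(grid, region) {
  box <- extract_box(grid, region$corner, region$shape)
  m <- mean(box$values)
  if (m <= 0) stopf("reference region mean %.4g is not positive; TNR undefined", m)
  m
}

#' TNR from the two regional means
#'
#' @param suv_t mean SUV of the hottest tumor region.
#' @param suv_n mean SUV of the reference region (> 0).
#' @return `suv_t / suv_n`.
#' @export
compute_tnr <- function(suv_t, suv_n) {
  if (!is.finite(suv_n) || suv_n <= 0) stopf("suv_n must be > 0")
  suv_t / suv_n
}

#' Full TNR quantification for one case
#'
#' @param grid a [voxel_grid()].
#' @param reference_region list with 0-based `corner` and `shape`.
#' @param target_volume window volume in cm^3.
#' @return A `tnr_result`: `suv_t`, `suv_n`, `tnr`, `t_region`, `n_region`.
#' @export
tnr_for_case <- function(grid, reference_region, target_volume = 1.0) {
  hot <- hottest_region_mean(grid, target_volume)
  suv_n <- reference_region_mean(grid, reference_region)
  structure(list(suv_t = hot$suv_t, suv_n = suv_n,
                 tnr = compute_tnr(hot$suv_t, suv_n),
                 t_region = hot$region, n_region = reference_region),
            class = "tnr_result")
}
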