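#' Voxel grid: a 3D scalar field of SUV values with physical spacing
#'
#' The unit every pipeline stage consumes. `values` is a 3D numeric array
#' (standardized uptake values, dimensionless), `spacing` the per-axis voxel
#' size in mm, `origin` the physical coordinate (mm) of voxel (0,0,0).
#'
#' @param values 3D numeric array; all values must be finite.
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param case_id opaque case label.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       case_id = "case") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stopf("'values' must be a 3D array")
  if (any(dim(values) < 1L)) stopf("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("'spacing' must be 3 strictly positive numbers (mm)")
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stopf("voxel grid contains %d non-finite voxel(s); mask or repair upstream", nbad)
  structure(
    list(values = values, spacing = spacing,
         origin = as.numeric(origin), case_id = as.character(case_id)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid '%s'> %dx%dx%d voxels, spacing %s mm, SUV range [%.4g, %.4g]\n",
              x$case_id, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param grid a [voxel_grid()].
#' @return Voxel volume in mm^3 (product of spacings).
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Extract a rectangular sub-volume (the tumor "parallelepiped")
#'
#' Indices are 0-based and boxes half-open `[corner, corner + shape)`, the
#' dominant scientific-array convention. The box must lie entirely inside the
#' grid; there is no silent clipping.
#'
#' @param grid a [voxel_grid()].
#' @param corner integer triple, 0-based index of the box corner.
#' @param shape integer triple of voxel counts, each >= 1.
#' @return A [voxel_grid()] with origin shifted by `corner * spacing`.
#' @export
extract_box <- function(grid, corner, shape) {
  corner <- as.integer(corner); shape <- as.integer(shape)
  if (length(corner) != 3L || length(shape) != 3L)
    stopf("'corner' and 'shape' must be integer triples")
  if (any(shape < 1L)) stopf("'shape' components must be >= 1")
  d <- dim(grid$values)
  if (any(corner < 0L) || any(corner + shape > d))
    stopf("box [%s)+%s exceeds grid extent %s",
          paste(corner, collapse = ","), paste(shape, collapse = ","),
          paste(d, collapse = "x"))
  idx <- Map(function(c0, s) seq.int(c0 + 1L, c0 + s), corner, shape)
  vals <- grid$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  voxel_grid(vals, grid$spacing, grid$origin + corner * grid$spacing,
             grid$case_id)
}

## ---- NIfTI I/O -------------------------------------------------------------
## Minimal single-volume NIfTI support written against the NIfTI-1.1 and
## NIfTI-2 header layouts. Only spacing and origin are modeled; header
## rotations/flips are not reoriented (all features downstream are
## direction-averaged). Gzipped files are handled transparently.

nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)) # uint16

#' Read a single 3D NIfTI volume
#'
#' Supports NIfTI-1 and NIfTI-2, plain or gzipped, little or big endian, for
#' the common scalar datatypes (uint8/int16/int32/uint16/float32/float64).
#' Header scaling (`scl_slope`/`scl_inter`) is applied. Trailing singleton
#' dimensions are squeezed; a genuine 4th dimension is rejected. Non-finite
#' voxels cause rejection with a count, never silent imputation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param case_id case label; defaults to the file name without extension.
#' @return A [voxel_grid()].
#' @export
read_nifti <- function(path, case_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", 4L)
  sizeof_hdr <- readBin(raw_hdr, "integer", 1L, 4L, endian = "little")
  endian <- "little"
  if (!sizeof_hdr %in% c(348L, 540L)) {
    sizeof_hdr <- readBin(raw_hdr, "integer", 1L, 4L, endian = "big")
    endian <- "big"
  }
  if (sizeof_hdr == 348L) {
    hdr <- read_nifti1_header(con, endian)
  } else if (sizeof_hdr == 540L) {
    hdr <- read_nifti2_header(con, endian)
  } else {
    stopf("%s is not a NIfTI-1 or NIfTI-2 file", path)
  }
  ndim <- hdr$dim[1]
  shape <- hdr$dim[seq.int(2L, 1L + max(ndim, 1L))]
  extra <- shape[-(1:3)]
  if (ndim < 3L || (length(extra) && any(extra > 1L)))
    stopf("%s: not a 3D scalar volume (dim = %s)", path,
          paste(hdr$dim[seq_len(ndim + 1L)], collapse = "x"))
  shape <- shape[1:3]
  dt <- nifti_dtypes[[as.character(hdr$datatype)]]
  if (is.null(dt)) stopf("%s: unsupported NIfTI datatype code %d", path, hdr$datatype)
  # seek is unreliable on gz connections: consume bytes up to vox_offset
  already <- if (sizeof_hdr == 348L) 348L else 540L
  skip <- hdr$vox_offset - already
  if (skip > 0) invisible(readBin(con, "raw", skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stopf("%s: truncated data section", path)
  if (is.finite(hdr$scl_slope) && is.finite(hdr$scl_inter) &&
      hdr$scl_slope != 0 && !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  nbad <- sum(!is.finite(vals))
  if (nbad > 0L) stopf("%s: %d non-finite voxel(s) rejected", path, nbad)
  spacing <- abs(hdr$pixdim[2:4])
  if (any(spacing <= 0)) stopf("%s: non-positive voxel spacing in header", path)
  voxel_grid(array(as.double(vals), dim = shape), spacing, hdr$origin,
             case_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

read_nifti1_header <- function(con, endian) {
  h <- readBin(con, "raw", 344L)                 # bytes 4..347
  int16 <- function(off, n) readBin(h[(off - 4L + 1L):length(h)], "integer", n, 2L, endian = endian)
  flt32 <- function(off, n) readBin(h[(off - 4L + 1L):length(h)], "double", n, 4L, endian = endian)
  dim <- int16(40L, 8L)
  list(dim = dim,
       datatype = int16(70L, 1L),
       pixdim = flt32(76L, 8L),
       vox_offset = as.integer(round(flt32(108L, 1L))),
       scl_slope = flt32(112L, 1L),
       scl_inter = flt32(116L, 1L),
       origin = nifti_origin(sform_code = int16(254L, 1L),
                             srow = flt32(280L, 12L),
                             qform_code = int16(252L, 1L),
                             qoffset = flt32(268L, 3L)))
}

read_nifti2_header <- function(con, endian) {
  h <- readBin(con, "raw", 536L)                 # bytes 4..539
  at <- function(off, len) h[(off - 4L + 1L):(off - 4L + len)]
  int16 <- function(off, n) readBin(at(off, 2L * n), "integer", n, 2L, endian = endian)
  int32 <- function(off, n) readBin(at(off, 4L * n), "integer", n, 4L, endian = endian)
  i64 <- function(off, n) {   # small non-negative int64 -> double
    w <- int32(off, 2L * n)
    lo <- w[seq(1L, 2L * n, 2L)]; hi <- w[seq(2L, 2L * n, 2L)]
    if (endian == "big") { tmp <- lo; lo <- hi; hi <- tmp }
    ifelse(lo < 0, lo + 2^32, lo) + 2^32 * hi
  }
  flt64 <- function(off, n) readBin(at(off, 8L * n), "double", n, 8L, endian = endian)
  list(dim = as.integer(i64(16L, 8L)),
       datatype = int16(12L, 1L),
       pixdim = flt64(104L, 8L),
       vox_offset = as.integer(i64(168L, 1L)),
       scl_slope = flt64(176L, 1L),
       scl_inter = flt64(184L, 1L),
       origin = nifti_origin(sform_code = int32(348L, 1L),
                             srow = flt64(400L, 12L),
                             qform_code = int32(344L, 1L),
                             qoffset = flt64(376L, 3L)))
}

nifti_origin <- function(sform_code, srow, qform_code, qoffset) {
  if (isTRUE(sform_code > 0)) srow[c(4L, 8L, 12L)]
  else if (isTRUE(qform_code > 0)) qoffset
  else c(0, 0, 0)
}

#' Write a voxel grid as a NIfTI-1 file
#'
#' Writes a canonical single-volume NIfTI-1 file (sform diagonal affine built
#' from spacing and origin, no rotation). `read_nifti(write_nifti(g))`
#' preserves shape, spacing and values up to the storage datatype.
#'
#' @param grid a [voxel_grid()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param dtype `"float64"` (lossless, default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  code <- if (dtype == "float64") 64L else 16L
  size <- if (dtype == "float64") 8L else 4L
  d <- dim(grid$values)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  wi32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wf32 <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi32(348L)                              # sizeof_hdr
  wraw(36L)                               # data_type..dim_info
  wi16(c(3L, d, 1L, 1L, 1L, 1L))          # dim[8]
  wf32(c(0, 0, 0)); wi16(0L)              # intent
  wi16(code); wi16(size * 8L); wi16(0L)   # datatype, bitpix, slice_start
  wf32(c(1, grid$spacing, 0, 0, 0, 0))    # pixdim[8] (qfac = 1)
  wf32(352); wf32(1); wf32(0)             # vox_offset, scl_slope, scl_inter
  wi16(0L); wraw(1L)                      # slice_end, slice_code
  writeBin(as.raw(2L), con)               # xyzt_units = mm
  wf32(c(0, 0, 0, 0)); wi32(c(0L, 0L))    # cal/slice_duration/toffset, glmax/glmin
  wraw(80L + 24L)                         # descrip, aux_file
  wi16(0L); wi16(1L)                      # qform_code = 0, sform_code = 1
  wf32(c(0, 0, 0, 0, 0, 0))               # quatern b,c,d + qoffset x,y,z
  wf32(c(grid$spacing[1], 0, 0, grid$origin[1],
         0, grid$spacing[2], 0, grid$origin[2],
         0, 0, grid$spacing[3], grid$origin[3]))
  wraw(16L)                               # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)      # magic "n+1\0"
  wraw(4L)                                # extension flag: none
  writeBin(as.double(grid$values), con, size, endian = "little")
  invisible(path)
}
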