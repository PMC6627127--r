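#' Create a 3D image volume
#'
#' Lightweight container for a 3D scalar grid with physical voxel spacing.
#' This is the common carrier for T2-weighted, ASL and single-b DWI frames.
#'
#' @param data Numeric 3D array (voxel values).
#' @param spacing Numeric length-3 vector, voxel edge lengths in mm
#'   (x, y, z).
#' @return An object of class `image_volume`: a list with elements `data`
#'   and `spacing`.
#' @export
image_volume <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Create a binary region-of-interest mask
#'
#' @param data Logical (or coercible) 3D array; `TRUE` marks in-ROI voxels.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  vol <- image_volume(array(0, dim(data)), spacing)
  structure(list(data = data, spacing = vol$spacing), class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, voxel %s mm>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s, %d voxels set, voxel %s mm>\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Create a multi-b-value DWI series
#'
#' @param b_values Strictly increasing, non-negative b-values in s/mm^2.
#' @param data 4D numeric array; the fourth dimension indexes b-values.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(b_values, data, spacing) {
  b_values <- as.numeric(b_values)
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (any(b_values < 0) || any(diff(b_values) <= 0))
    stop("b-values must be non-negative and strictly increasing")
  if (dim(data)[4] != length(b_values))
    stop("fourth array dimension must match the number of b-values")
  vol <- image_volume(array(0, dim(data)[1:3]), spacing)
  structure(list(b_values = b_values, data = data, spacing = vol$spacing),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series %s, %d b-values (%g-%g s/mm2)>\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              length(x$b_values), min(x$b_values), max(x$b_values)))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data)[1:3], dim(b$data)[1:3]) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch between %s (dims/spacing differ)", what))
  invisible(TRUE)
}

#' ROI-restricted voxel values
#'
#' @param vol An `image_volume`.
#' @param mask A `roi_mask` aligned to `vol`.
#' @param exclude Optional `roi_mask` of voxels to drop (e.g. necrotic or
#'   cystic areas flagged during delineation).
#' @return Numeric vector of in-ROI voxel values.
#' @export
mask_values <- function(vol, mask, exclude = NULL) {
  check_same_geometry(vol, mask, "volume and mask")
  keep <- mask$data
  if (!is.null(exclude)) {
    check_same_geometry(mask, exclude, "mask and exclusion mask")
    keep <- keep & !exclude$data
  }
  if (!any(keep)) stop("mask is empty (after exclusions)")
  vol$data[keep]
}
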