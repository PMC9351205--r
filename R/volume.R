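#' CT volume container
#'
#' A 3D scalar field in Hounsfield units with per-axis voxel spacing.
#' The array is indexed `[z, y, x]` with `z = 1` the most superior slice
#' and increasing `x` the patient's left.
#'
#' @param data numeric 3D array, `dim = c(nz, ny, nx)`.
#' @param spacing_mm numeric length-3, voxel spacing in mm for (z, y, x).
#' @return an object of class `ct_volume` with fields `data` and `spacing_mm`.
#' @export
ct_volume <- function(data, spacing_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0))
  structure(list(data = data, spacing_mm = spacing_mm), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z,y,x), spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Resample a CT volume to a new voxel spacing
#'
#' Trilinear interpolation on a cell-centered grid.  `new_spacing_mm` entries
#' set to `NA` keep the original spacing on that axis.
#'
#' @param vol a [ct_volume].
#' @param new_spacing_mm numeric length-3 target spacing (z, y, x) in mm.
#' @return a resampled [ct_volume].
#' @export
resample_volume <- function(vol, new_spacing_mm) {
  stopifnot(inherits(vol, "ct_volume"), length(new_spacing_mm) == 3)
  sp <- ifelse(is.na(new_spacing_mm), vol$spacing_mm, as.numeric(new_spacing_mm))
  d <- dim(vol$data)
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing_mm / sp)))
  v <- .resample_trilinear(as.numeric(vol$data), as.integer(d), out_dim)
  ct_volume(array(v, out_dim), spacing_mm = sp)
}

# Bounding box of a logical mask, 0-based half-open [min, max) in (z, y, x).
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) stop("mask is empty; no bounding box")
  list(min = as.integer(apply(w, 2, min) - 1L),
       max = as.integer(apply(w, 2, max)))
}

# Dice overlap of two logical arrays of equal shape.
#' Dice similarity coefficient of two binary masks
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
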