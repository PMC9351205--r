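# Per-patient patch extraction: four 64-voxel landmark cubes, five lobe
# patches, one tumor patch; all normalized to [0, 1].

PATCH_SIZE <- 64L
HU_CLIP <- c(-1000, 400)   # lung window: lumen through soft tissue
PAD_HU <- -1000            # out-of-volume is physically air/absence

PATCH_ROLES <- c("ROOT", "CENTER", "LEFT", "RIGHT",
                 "LUL", "LLL", "RUL", "RML", "RLL", "TUMOR")

#' Normalize Hounsfield units to \[0, 1\]
#'
#' Clips to the lung window (-1000, 400) HU and min-max scales.  Output
#' carries a `normalized` attribute and is returned unchanged if already
#' normalized (idempotence is tracked by the flag: the affine map itself is
#' not a projection).
#'
#' @param values numeric vector/array of HU values.
#' @return values in \[0, 1\] with `attr(, "normalized") = TRUE`.
#' @export
normalize_hu <- function(values) {
  if (isTRUE(attr(values, "normalized"))) return(values)
  out <- (pmin(pmax(values, HU_CLIP[1]), HU_CLIP[2]) - HU_CLIP[1]) /
    (HU_CLIP[2] - HU_CLIP[1])
  if (!is.null(dim(values))) dim(out) <- dim(values)
  attr(out, "normalized") <- TRUE
  out
}

new_patch <- function(values, role, source_bbox) {
  stopifnot(all(dim(values) == PATCH_SIZE), role %in% PATCH_ROLES)
  structure(list(values = values, role = role, source_bbox = source_bbox),
            class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("<patch> role %s, %s, values [%.3f, %.3f]\n", x$role,
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Crop a 64-voxel cube centered on a landmark
#'
#' The landmark sits at 0-based patch index `size/2` on each axis; regions
#' outside the volume are padded with -1000 HU (air) before normalization.
#'
#' @param ct a [ct_volume].
#' @param point 1-based voxel (z, y, x).
#' @param role patch role tag.
#' @param size cube edge in voxels.
#' @return a `patch`.
#' @export
crop_landmark_patch <- function(ct, point, role = "CENTER", size = PATCH_SIZE) {
  stopifnot(inherits(ct, "ct_volume"), length(point) == 3)
  d <- dim(ct$data)
  if (any(point < 1 | point > d)) stop("landmark point outside the volume")
  half <- size %/% 2
  lo0 <- as.integer(point - 1L - half)          # 0-based inclusive start
  hi0 <- lo0 + size                              # 0-based exclusive end
  out <- array(PAD_HU, rep(size, 3))
  src_lo <- pmax(lo0, 0L); src_hi <- pmin(hi0, d)
  if (all(src_hi > src_lo)) {
    dst <- lapply(1:3, function(a) (src_lo[a] - lo0[a] + 1L):(src_hi[a] - lo0[a]))
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      ct$data[(src_lo[1] + 1L):src_hi[1],
              (src_lo[2] + 1L):src_hi[2],
              (src_lo[3] + 1L):src_hi[3]]
  }
  new_patch(normalize_hu(out), role, list(min = lo0, max = hi0))
}

# Crop a 0-based half-open bbox (clipped to the volume), returning the array.
crop_bbox <- function(arr, bbox) {
  d <- dim(arr)
  lo <- pmax(bbox$min, 0L); hi <- pmin(bbox$max, d)
  if (any(hi <= lo)) stop("empty bounding box")
  arr[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3], drop = FALSE]
}

#' Crop and resample the tumor patch
#'
#' Crops the radiologist-style bounding box and trilinearly resamples it to
#' a 64-voxel cube.
#'
#' @param ct a [ct_volume].
#' @param ann tumor annotation: list with `bbox` (`min`, `max`, 0-based
#'   half-open) and `lobes`.
#' @return a `patch` with role `"TUMOR"`.
#' @export
crop_tumor_patch <- function(ct, ann) {
  stopifnot(inherits(ct, "ct_volume"))
  bbox <- ann$bbox
  if (any(bbox$max <= bbox$min)) stop("empty tumor bounding box")
  d <- dim(ct$data)
  if (any(bbox$min < 0) || any(bbox$max > d))
    stop("tumor bounding box extends outside the volume")
  sub <- crop_bbox(ct$data, bbox)
  vals <- array(.resample_trilinear(as.numeric(sub), as.integer(dim(sub)),
                                    rep(PATCH_SIZE, 3L)), rep(PATCH_SIZE, 3))
  new_patch(normalize_hu(vals), "TUMOR", bbox)
}

#' Crop and resample a lobe patch
#'
#' Takes the bounding box of the lobe mask, replaces voxels outside the
#' lobe with -1000 HU, and resamples to a 64-voxel cube.
#'
#' @param ct a [ct_volume].
#' @param lobe_labels integer label volume (0 background, 1..5 lobes).
#' @param lobe_id lobe label in 1..5.
#' @return a `patch` with the lobe's role (LUL/LLL/RUL/RML/RLL).
#' @export
crop_lobe_patch <- function(ct, lobe_labels, lobe_id) {
  stopifnot(inherits(ct, "ct_volume"), lobe_id %in% 1:5)
  mask <- lobe_labels == lobe_id
  if (!any(mask))
    stop(sprintf("lobe %s (label %d) absent from the label map",
                 LOBE_NAMES[lobe_id], lobe_id))
  bbox <- mask_bbox(mask)
  sub <- crop_bbox(ct$data, bbox)
  sub_mask <- crop_bbox(mask, bbox)
  sub[!sub_mask] <- PAD_HU
  vals <- array(.resample_trilinear(as.numeric(sub), as.integer(dim(sub)),
                                    rep(PATCH_SIZE, 3L)), rep(PATCH_SIZE, 3))
  new_patch(normalize_hu(vals), LOBE_NAMES[lobe_id], bbox)
}

#' Extract all ten patches for one patient
#'
#' Four airway landmark cubes, five lobe patches, one tumor patch — the ten
#' node images of the lung graph, in canonical role order.
#'
#' @param ct a [ct_volume].
#' @param landmarks a `landmark_set`.
#' @param lobe_labels integer label volume.
#' @param tumor_annotation list with `bbox` and `lobes`.
#' @return named list of ten `patch` objects (names = roles).
#' @export
patient_patches <- function(ct, landmarks, lobe_labels, tumor_annotation) {
  patches <- list(
    ROOT = crop_landmark_patch(ct, landmarks$root, "ROOT"),
    CENTER = crop_landmark_patch(ct, landmarks$center, "CENTER"),
    LEFT = crop_landmark_patch(ct, landmarks$left, "LEFT"),
    RIGHT = crop_landmark_patch(ct, landmarks$right, "RIGHT"))
  for (lobe in 1:5) patches[[LOBE_NAMES[lobe]]] <- crop_lobe_patch(ct, lobe_labels, lobe)
  patches$TUMOR <- crop_tumor_patch(ct, tumor_annotation)
  patches[PATCH_ROLES]
}
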