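# Airway tree segmentation and landmark extraction.
#
# The trachea seed is found deterministically (centroid of the largest
# non-boundary air component in the superior quarter of the volume) rather
# than by random picking: reproducibility, and the downstream landmark
# logic requires the seed to be inside the airway anyway.

#' Select a trachea seed voxel
#'
#' Scans the superior quarter of the volume for sub--950 HU components,
#' discards components touching the in-plane boundary (ambient air), and
#' returns the voxel of the largest remaining component nearest its own
#' most-superior-slice centroid.  Deterministic.
#'
#' @param ct a [ct_volume].
#' @param air_hu threshold below which a voxel counts as air.
#' @return 1-based voxel coordinate (z, y, x) inside the trachea lumen.
#' @export
select_seed <- function(ct, air_hu = -950) {
  stopifnot(inherits(ct, "ct_volume"))
  d <- dim(ct$data)
  slab_nz <- max(2L, floor(d[1] / 4))
  slab <- ct$data[seq_len(slab_nz), , , drop = FALSE] < air_hu
  lab <- .cc_label26(as.logical(slab), as.integer(dim(slab)))
  k <- attr(lab, "n_components")
  if (k == 0) stop("trachea not found: no air component in the superior quarter")
  lab <- array(lab, dim(slab))
  # drop components touching the in-plane (y/x) boundary: ambient air
  edge <- unique(c(lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  edge <- edge[edge != 0]
  sizes <- tabulate(lab, nbins = k)
  sizes[edge] <- 0L
  if (all(sizes == 0)) stop("trachea not found: only boundary air present")
  comp <- which.max(sizes)
  vox <- which(lab == comp, arr.ind = TRUE)
  z0 <- min(vox[, 1])
  top <- vox[vox[, 1] == z0, , drop = FALSE]
  ctr <- colMeans(top)
  # nearest-to-centroid voxel that is deep air (safe under noise for the
  # region-growing start threshold); fall back to the darkest voxel
  hu <- ct$data[top]
  deep <- hu < -980
  if (any(deep)) {
    cand <- top[deep, , drop = FALSE]
    pick <- cand[which.min(colSums((t(cand) - ctr)^2)), ]
  } else {
    pick <- top[which.min(hu), ]
  }
  as.integer(pick)
}

#' Segment the airway tree by adaptive region growing
#'
#' Grows a 26-connected region from the seed, admitting voxels with HU
#' strictly below a threshold that is relaxed upward from `start_hu` in
#' `step_hu` increments.  A step that multiplies the mask volume by more
#' than `explosion` (a leak into the parenchyma) is rolled back and growth
#' stops; the final mask is the last pre-explosion mask.
#'
#' @param ct a [ct_volume].
#' @param seed 1-based voxel (z, y, x), e.g. from [select_seed].
#' @param policy list: `start_hu` (-980), `step_hu` (20), `max_hu` (-500),
#'   `explosion` (2.0), `boundary_frac` (0.4).
#' @return a `binary_mask`: logical array `voxels` + `spacing_mm` +
#'   `final_threshold_hu`.
#' @export
region_grow <- function(ct, seed,
                        policy = list(start_hu = -980, step_hu = 20,
                                      max_hu = -500, explosion = 2.0,
                                      boundary_frac = 0.4)) {
  stopifnot(inherits(ct, "ct_volume"), length(seed) == 3)
  d <- dim(ct$data)
  if (any(seed < 1 | seed > d)) stop("seed outside the volume")
  res <- .region_grow(as.numeric(ct$data), as.integer(d),
                      as.integer(seed - 1L),
                      policy$start_hu, policy$step_hu, policy$max_hu,
                      policy$explosion, policy$boundary_frac)
  if (res$status == 3)
    stop(sprintf("seed HU (%.0f) is not below the starting threshold (%.0f)",
                 ct$data[seed[1], seed[2], seed[3]], policy$start_hu))
  if (res$status == 2)
    stop("region growing leaked onto the volume boundary (mask floods)")
  structure(list(voxels = array(res$mask, d),
                 spacing_mm = ct$spacing_mm,
                 final_threshold_hu = res$final_thr),
            class = "binary_mask")
}

#' Skeletonize a binary airway mask
#'
#' Distance-ordered homotopic thinning: border voxels are peeled in
#' increasing distance-transform order when their removal preserves local
#' topology (simple points) and they are not curve endpoints.  The result
#' is a unit-wide, connected centerline contained in the mask.
#'
#' @param mask a `binary_mask` from [region_grow] (or a logical array).
#' @param spacing_mm required when `mask` is a bare array.
#' @return a `skeleton`: `points` (n x 3 matrix of 1-based (z, y, x)),
#'   `graph` (igraph over 26-adjacent skeleton voxels), `degree`,
#'   `shape`, `spacing_mm`.
#' @export
skeletonize <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "binary_mask")) {
    vox <- mask$voxels; spacing_mm <- mask$spacing_mm
  } else {
    vox <- mask
    if (is.null(spacing_mm)) spacing_mm <- c(1, 1, 1)
  }
  if (!any(vox)) stop("cannot skeletonize an empty mask")
  skel <- array(.skeletonize3d(as.logical(vox), as.integer(dim(vox))), dim(vox))
  skeleton_from_voxels(skel, spacing_mm)
}

# Build the skeleton object (points + 26-adjacency igraph) from a voxel mask.
skeleton_from_voxels <- function(skel, spacing_mm) {
  pts <- which(skel, arr.ind = TRUE)
  colnames(pts) <- c("z", "y", "x")
  n <- nrow(pts)
  idx <- array(0L, dim(skel))
  idx[pts] <- seq_len(n)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 |
           (offs[, 1] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 3] > 0)))), ,
           drop = FALSE]   # half the neighborhood: each pair once
  edges <- NULL
  d <- dim(skel)
  for (k in seq_len(nrow(offs))) {
    q <- sweep(pts, 2, offs[k, ], "+")
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
          q[, 3] >= 1 & q[, 3] <= d[3]
    if (!any(ok)) next
    j <- idx[q[ok, , drop = FALSE]]
    hit <- j > 0
    if (any(hit)) edges <- rbind(edges, cbind(which(ok)[hit], j[hit]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  structure(list(points = pts, graph = g,
                 degree = igraph::degree(g),
                 shape = d, spacing_mm = spacing_mm),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d points, %d endpoints, %d branch points\n",
              nrow(x$points), sum(x$degree <= 1), sum(x$degree >= 3)))
  invisible(x)
}

#' Prune short skeleton spurs
#'
#' Removes terminal branches shorter than `min_len` voxels (geodesic hops
#' from an endpoint to the nearest branch point): thinning artifacts create
#' fake branch points that would confuse the carina search.
#'
#' @param skel a `skeleton`.
#' @param min_len spurs strictly shorter than this many voxels are removed.
#' @return a pruned `skeleton`.
#' @export
prune_spurs <- function(skel, min_len = 5L) {
  repeat {
    deg <- igraph::degree(skel$graph)
    branch <- which(deg >= 3)
    if (length(branch) == 0) return(skel)
    ends <- which(deg == 1)
    if (length(ends) == 0) return(skel)
    dmat <- igraph::distances(skel$graph, v = ends, to = branch)
    drop <- integer(0)
    for (i in seq_along(ends)) {
      dist_b <- min(dmat[i, ])
      if (is.finite(dist_b) && dist_b < min_len) {
        b <- branch[which.min(dmat[i, ])]
        path <- igraph::shortest_paths(skel$graph, from = ends[i], to = b)$vpath[[1]]
        drop <- c(drop, setdiff(as.integer(path), b))
      }
    }
    drop <- unique(drop)
    if (length(drop) == 0) return(skel)
    keep <- setdiff(seq_len(nrow(skel$points)), drop)
    vox <- array(FALSE, skel$shape)
    vox[skel$points[keep, , drop = FALSE]] <- TRUE
    skel <- skeleton_from_voxels(vox, skel$spacing_mm)
  }
}

#' Extract the four airway landmarks
#'
#' Root = most superior endpoint; center = the branch point (degree >= 3)
#' closest to the root along the skeleton (the carina); left/right = for
#' each subtree leaving the carina, the skeleton point at maximal geodesic
#' distance from it (the distal main-bronchus points), with sides assigned
#' by x relative to the carina (increasing x = patient-left).
#'
#' The supplementary search procedure of the source method is not public;
#' this reconstruction follows the stated root/carina/distal definitions.
#'
#' @param skel a `skeleton` (spurs are pruned first, see [prune_spurs]).
#' @param min_spur spur-pruning length.
#' @return a `landmark_set`: `root`, `center`, `left`, `right`, each a
#'   1-based (z, y, x) voxel coordinate.
#' @export
extract_landmarks <- function(skel, min_spur = 5L) {
  stopifnot(inherits(skel, "skeleton"))
  skel <- prune_spurs(skel, min_spur)
  deg <- igraph::degree(skel$graph)
  if (!any(deg >= 3)) stop("carina not found: skeleton has no branch point")
  ends <- which(deg <= 1)
  if (length(ends) == 0) stop("carina not found: skeleton has no endpoints")
  root <- ends[which.min(skel$points[ends, "z"])]
  branch <- which(deg >= 3)
  d_root <- igraph::distances(skel$graph, v = root, to = branch)[1, ]
  center <- branch[which.min(d_root)]

  # distal main-bronchus points: the deepest skeleton point (geodesic from
  # the carina) on each side of the carina's sagittal plane, excluding the
  # root's own branch
  dist_c <- igraph::distances(skel$graph, v = center)[1, ]
  dist_r <- igraph::distances(skel$graph, v = root)[1, ]
  cx <- skel$points[center, "x"]
  # a point is "below" the carina if its geodesic to the root passes the
  # carina (dist_r = dist_c + dist to carina, within 26-connectivity slack)
  below <- which(dist_r >= dist_c + dist_c[root] - 2 & dist_c > 0)
  left_side <- below[skel$points[below, "x"] > cx]
  right_side <- below[skel$points[below, "x"] < cx]
  if (length(left_side) == 0 || length(right_side) == 0)
    stop("carina not found: no subtree on one side of the branch point")
  left <- left_side[which.max(dist_c[left_side])]
  right <- right_side[which.max(dist_c[right_side])]
  structure(list(root = as.integer(skel$points[root, ]),
                 center = as.integer(skel$points[center, ]),
                 left = as.integer(skel$points[left, ]),
                 right = as.integer(skel$points[right, ])),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  for (nm in c("root", "center", "left", "right"))
    cat(sprintf("%7s: (%s)\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Write landmarks as JSON (0-based voxel indices)
#' @param lm a `landmark_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  jsonlite::write_json(lapply(lm[c("root", "center", "left", "right")],
                              function(p) as.integer(p - 1L)),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' Read landmarks written by [write_landmarks] (back to 1-based)
#' @param path JSON path.
#' @return a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(j[c("root", "center", "left", "right")],
                   function(p) as.integer(p + 1L)),
            class = "landmark_set")
}
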