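# Node features: 64^3 patch -> convolutional encoder -> global average
# pooling to 1024 -> ridge-shrunk principal-component reduction to 96.
#
# The reference pipeline used a pretrained 3D ResNet feature extractor;
# pretrained weights are an external artifact, so the default encoder here
# is a small fixed-seed randomly-initialized 3D conv net with the same
# 1024-channel output contract.  `encoder` is an interface: any object with
# the same fields (and a compatible forward) can be plugged in.

RAW_DIM <- 1024L
NODE_DIM <- 96L

#' Default patch encoder
#'
#' Three-layer 3D conv net: 3x3x3 stride-2 conv (1→8, ReLU), 3x3x3 stride-2
#' conv (8→16, ReLU), then a 1x1x1 channel expansion to `channels`.  Weights
#' are He-initialized from a fixed seed so the encoder is a deterministic,
#' dependency-free stand-in for a pretrained feature extractor.
#'
#' @param seed weight-initialization seed.
#' @param channels output channel count (the raw feature length).
#' @return a `patch_encoder`.
#' @export
default_encoder <- function(seed = 42L, channels = RAW_DIM) {
  with_seed(seed, {
    he <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))
    k <- 3L
    structure(list(
      name = sprintf("random-cnn-seed%d", seed),
      channels = as.integer(channels),
      conv1 = list(w = he(8 * 1 * k^3, k^3), dims = c(8L, 1L, k), b = rep(0, 8)),
      conv2 = list(w = he(16 * 8 * k^3, 8 * k^3), dims = c(16L, 8L, k), b = rep(0, 16)),
      proj = matrix(he(channels * 16, 16), nrow = channels)
    ), class = "patch_encoder")
  })
}

#' @export
print.patch_encoder <- function(x, ...) {
  cat(sprintf("<patch_encoder> %s, %d output channels\n", x$name, x$channels))
  invisible(x)
}

#' Run the encoder, returning its spatial feature map
#'
#' @param enc a `patch_encoder`.
#' @param patch a `patch` (or a 64^3 array of normalized values).
#' @return a `channels x n_voxels` matrix (the spatial output before pooling).
#' @export
encoder_forward <- function(enc, patch) {
  vals <- if (inherits(patch, "patch")) patch$values else patch
  if (!(is.array(vals) && all(dim(vals) == PATCH_SIZE)))
    stop(sprintf("encoder expects a %d^3 patch", PATCH_SIZE))
  h1 <- .conv3d_valid(as.numeric(vals), c(1L, dim(vals)),
                      enc$conv1$w, as.integer(enc$conv1$dims), enc$conv1$b,
                      2L, TRUE)
  h2 <- .conv3d_valid(h1$values, h1$dims,
                      enc$conv2$w, as.integer(enc$conv2$dims), enc$conv2$b,
                      2L, TRUE)
  spatial <- matrix(h2$values, ncol = h2$dims[1])  # n_voxels x 16
  enc$proj %*% t(spatial)                          # channels x n_voxels
}

#' Global average pooling over the spatial axis
#' @param feature_map `channels x n_voxels` matrix.
#' @return numeric vector of length `channels`.
#' @export
pool_features <- function(feature_map) rowMeans(feature_map)

#' Encode a patch into a raw 1024-d feature
#'
#' Encoder forward pass followed by global average pooling.  Deterministic.
#'
#' @param patch a `patch`.
#' @param enc a `patch_encoder` (default: [default_encoder]).
#' @return numeric vector of length `enc$channels` (1024 by default).
#' @export
encode_patch <- function(patch, enc = default_encoder()) {
  # the 1x1x1 channel expansion commutes with global average pooling, so
  # pool the 16-channel map first (identical result, far less memory)
  vals <- if (inherits(patch, "patch")) patch$values else patch
  if (!(is.array(vals) && all(dim(vals) == PATCH_SIZE)))
    stop(sprintf("encoder expects a %d^3 patch", PATCH_SIZE))
  h1 <- .conv3d_valid(as.numeric(vals), c(1L, dim(vals)),
                      enc$conv1$w, as.integer(enc$conv1$dims), enc$conv1$b,
                      2L, TRUE)
  h2 <- .conv3d_valid(h1$values, h1$dims,
                      enc$conv2$w, as.integer(enc$conv2$dims), enc$conv2$b,
                      2L, TRUE)
  pooled16 <- colMeans(matrix(h2$values, ncol = h2$dims[1]))
  v <- as.numeric(enc$proj %*% pooled16)
  if (!all(is.finite(v))) stop("non-finite raw feature")
  v
}

#' Fit the ridge-shrunk principal-component reducer
#'
#' Centers the training rows and projects onto the top `out_dim` principal
#' directions, with direction i shrunk by `s_i^2 / (s_i^2 + lambda)` (s_i =
#' singular value of the centered matrix).  `lambda = 0` gives plain
#' rank-`out_dim` PCA scores.  When the training rank is below `out_dim`
#' the remaining directions are zero (they carry no variance).  Sign
#' convention: each direction's largest-magnitude loading is positive.
#'
#' @param train_matrix `n x p` matrix of raw features (training rows only).
#' @param lambda ridge penalty, >= 0.
#' @param out_dim output dimension (96).
#' @param fitted_on identifier(s) of the training set, kept for leakage
#'   bookkeeping.
#' @return a `ridge_reducer`: `projection` (`p x out_dim`), `center`,
#'   `lambda`, `out_dim`, `fitted_on`, `singular_values`.
#' @export
fit_reducer <- function(train_matrix, lambda = 1, out_dim = NODE_DIM,
                        fitted_on = "unspecified") {
  train_matrix <- as.matrix(train_matrix)
  p <- ncol(train_matrix)
  if (out_dim > p) stop(sprintf("out_dim (%d) exceeds input dimension (%d)", out_dim, p))
  if (lambda < 0) stop("lambda must be >= 0")
  center <- colMeans(train_matrix)
  xc <- sweep(train_matrix, 2, center)
  k_max <- min(dim(xc))
  sv <- svd(xc, nu = 0, nv = k_max)
  k <- min(out_dim, k_max)
  v <- sv$v[, seq_len(k), drop = FALSE]
  # fix signs: largest-magnitude loading positive
  for (j in seq_len(k)) {
    m <- which.max(abs(v[, j]))
    if (v[m, j] < 0) v[, j] <- -v[, j]
  }
  s2 <- sv$d[seq_len(k)]^2
  shrink <- if (lambda == 0) rep(1, k) else s2 / (s2 + lambda)
  shrink[s2 <= .Machine$double.eps * max(s2, 1)] <- 0
  proj <- matrix(0, p, out_dim)
  proj[, seq_len(k)] <- sweep(v, 2, shrink, "*")
  structure(list(projection = proj, center = center, lambda = lambda,
                 out_dim = as.integer(out_dim), fitted_on = fitted_on,
                 singular_values = sv$d[seq_len(k)]),
            class = "ridge_reducer")
}

#' @export
print.ridge_reducer <- function(x, ...) {
  cat(sprintf("<ridge_reducer> %d -> %d, lambda %.3g, fitted on: %s\n",
              length(x$center), x$out_dim, x$lambda,
              paste(head(x$fitted_on, 3), collapse = ", ")))
  invisible(x)
}

#' Apply a fitted reducer to raw features
#'
#' `(raw - center) %*% projection`; never refits.  The training mean maps
#' to the zero vector.
#'
#' @param r a `ridge_reducer`.
#' @param raw length-`p` vector or `n x p` matrix.
#' @return length-`out_dim` vector (or `n x out_dim` matrix).
#' @export
apply_reducer <- function(r, raw) {
  stopifnot(inherits(r, "ridge_reducer"))
  if (is.matrix(raw)) {
    sweep(raw, 2, r$center) %*% r$projection
  } else {
    as.numeric((raw - r$center) %*% r$projection)
  }
}

#' Persist a reducer as text (TSV payload + JSON metadata)
#' @param r a `ridge_reducer`.
#' @param stem output path stem; writes `<stem>.json` and `<stem>.tsv`.
#' @return `stem`, invisibly.
#' @export
save_reducer <- function(r, stem) {
  jsonlite::write_json(list(lambda = r$lambda, out_dim = r$out_dim,
                            fitted_on = r$fitted_on,
                            singular_values = r$singular_values),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".tsv"), "w")
  on.exit(close(con))
  writeLines(c(paste(sprintf("%.17g", r$center), collapse = "\t"),
               apply(r$projection, 2, function(col)
                 paste(sprintf("%.17g", col), collapse = "\t"))), con)
  invisible(stem)
}

#' Load a reducer saved by [save_reducer]
#' @param stem path stem.
#' @return a `ridge_reducer`.
#' @export
load_reducer <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(stem, ".tsv"))
  num <- lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric)
  center <- num[[1]]
  proj <- do.call(cbind, num[-1])
  structure(list(projection = proj, center = center, lambda = meta$lambda,
                 out_dim = as.integer(meta$out_dim), fitted_on = meta$fitted_on,
                 singular_values = meta$singular_values),
            class = "ridge_reducer")
}
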