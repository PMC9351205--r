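# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small, fast phantom (96^3 @ 1.25 mm, 120 mm extent) used across the
# airway/sampling tests.
small_spec <- function(seed = 3, noise_sd_hu = 20, ...) {
  phantom_spec(volume_shape = c(96, 96, 96), spacing_mm = c(1.25, 1.25, 1.25),
               tumor = list(lobe = 1L, diameter_mm = 18, intensity_offset_hu = 0),
               noise_sd_hu = noise_sd_hu, seed = seed, ...)
}

small_phantom <- function() cached("small_phantom", generate_phantom(small_spec()))
small_phantom_clean <- function() {
  cached("small_phantom_clean", generate_phantom(small_spec(noise_sd_hu = 0)))
}

# Straight vertical tube mask (no bifurcation), for skeleton tests.
tube_mask <- function(len = 40, radius = 3, dims = c(60, 31, 31)) {
  arr <- array(FALSE, dims)
  cy <- 16; cx <- 16
  circ <- expand.grid(y = 1:dims[2], x = 1:dims[3])
  circ <- circ[(circ$y - cy)^2 + (circ$x - cx)^2 <= radius^2, ]
  for (z in seq_len(len))
    arr[cbind(z, circ$y, circ$x)] <- TRUE
  arr
}

# Toy labeled graphs with the signal planted directly in the node features
# (bypasses the imaging stages; for GCN unit tests).  Each role has a fixed
# feature prototype — as real encoded patches do — with the planted severity
# shifting the TUMOR node and, more weakly, its host lobe.
toy_graphs <- function(n, dim = 6, seed = 1, signal = TRUE) {
  with_seed(seed, {
    proto <- matrix(rnorm(10 * dim, 0, 1), 10, dim)
    rownames(proto) <- node_roles()
    lapply(seq_len(n), function(i) {
      feat <- proto + matrix(rnorm(10 * dim, 0, 0.3), 10, dim)
      host <- sample(lobe_roles(), 1)
      s <- rnorm(1)
      if (signal) {
        feat["TUMOR", ] <- feat["TUMOR", ] + s
        feat[host, ] <- feat[host, ] + 0.5 * s
      }
      label <- rbinom(1, 1, stats::plogis(3 * s))
      build_graph(feat, host, sprintf("T%03d", i), label = label)
    })
  })
}

# Balanced variant guaranteeing both classes.
toy_graph_sets <- function(n_train = 80, n_val = 30, dim = 6, seed = 1) {
  gs <- toy_graphs(n_train + n_val, dim = dim, seed = seed)
  list(train = gs[seq_len(n_train)], val = gs[n_train + seq_len(n_val)])
}

# Bare patch wrapper for encoder tests (values assumed already in [0, 1]).
new_patch_for_test <- function(vals) {
  structure(list(values = vals, role = "TUMOR", source_bbox = NULL),
            class = "patch")
}
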