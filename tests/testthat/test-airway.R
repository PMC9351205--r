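# Airway segmentation, skeletonization and landmark extraction.

test_that("seed selection lands inside the trachea lumen", {
  s <- small_phantom()
  seed <- select_seed(s$ct)
  expect_true(s$airway_truth[seed[1], seed[2], seed[3]])
})

test_that("seed selection fails cleanly without an air tube", {
  flat <- ct_volume(array(-800, c(64, 64, 64)))
  expect_error(select_seed(flat), "trachea not found")
})

test_that("a laterally shifted phantom shifts the seed with it", {
  base <- generate_phantom(small_spec(seed = 6))
  shifted <- generate_phantom(small_spec(
    seed = 6, trachea = list(radius_mm = 4, length_mm = 40,
                             entry_frac = c(0.5, 0.62))))
  s1 <- select_seed(base$ct); s2 <- select_seed(shifted$ct)
  expect_gt(s2[3], s1[3] + 5)
  expect_true(shifted$airway_truth[s2[1], s2[2], s2[3]])
})

test_that("region growing recovers the airway tree (Dice >= 0.9, noise-free)", {
  s <- small_phantom_clean()
  mask <- region_grow(s$ct, select_seed(s$ct))
  expect_s3_class(mask, "binary_mask")
  expect_gte(dice(mask$voxels, s$airway_truth), 0.9)
  lab <- lungraph:::`.cc_label26`(as.logical(mask$voxels), dim(mask$voxels))
  expect_identical(attr(lab, "n_components"), 1L)
})

test_that("region growing rejects a parenchyma seed and floods on uniform air", {
  s <- small_phantom_clean()
  lung_vox <- which(s$lobe_labels == 2L & !s$airway_truth, arr.ind = TRUE)[1, ]
  expect_error(region_grow(s$ct, lung_vox), "not below the starting threshold")
  uniform <- ct_volume(array(-1000, c(64, 64, 64)))
  expect_error(region_grow(uniform, c(32, 32, 32)), "leak")
})

test_that("skeleton of a straight tube is its axis", {
  msk <- tube_mask(len = 40, radius = 2)
  sk <- prune_spurs(skeletonize(msk, spacing_mm = c(1, 1, 1)))
  # contained in the mask
  expect_true(all(msk[sk$points]))
  # point count within +-2 of the tube length
  expect_lte(abs(nrow(sk$points) - 40), 2)
  # interior points within 1 voxel of the designed axis (y = x = 16);
  # homotopic thinning leaves end-cap effects within the tube radius
  interior <- sk$points[, "z"] > 2 & sk$points[, "z"] < 38
  expect_true(all(abs(sk$points[interior, "y"] - 16) <= 1))
  expect_true(all(abs(sk$points[interior, "x"] - 16) <= 1))
  expect_true(all(abs(sk$points[, "y"] - 16) <= 2))
  expect_true(all(abs(sk$points[, "x"] - 16) <= 2))
  expect_true(igraph::is_connected(sk$graph))
})

test_that("single-voxel mask skeletonizes to itself; empty mask errors", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  sk <- skeletonize(one, spacing_mm = c(1, 1, 1))
  expect_identical(nrow(sk$points), 1L)
  expect_identical(as.integer(sk$points[1, ]), c(3L, 3L, 3L))
  expect_error(skeletonize(array(FALSE, c(5, 5, 5))), "empty")
})

test_that("Y-tree skeleton has exactly one branch point after pruning", {
  s <- small_phantom_clean()
  mask <- region_grow(s$ct, select_seed(s$ct))
  sk <- prune_spurs(skeletonize(mask))
  expect_identical(sum(igraph::degree(sk$graph) >= 3), 1L)
  expect_identical(sum(igraph::degree(sk$graph) <= 1), 3L)
})

test_that("landmarks match the phantom design (carina within 3 voxels)", {
  s <- small_phantom_clean()
  mask <- region_grow(s$ct, select_seed(s$ct))
  lm <- extract_landmarks(skeletonize(mask))
  expect_lte(sqrt(sum((lm$center - s$landmarks_truth$center)^2)), 3)
  expect_lt(lm$root[1], lm$center[1])                 # root superior to carina
  expect_true(lm$left[3] > lm$center[3])              # patient-left: larger x
  expect_true(lm$right[3] < lm$center[3])
})

test_that("a straight tube has no carina", {
  sk <- skeletonize(tube_mask(), spacing_mm = c(1, 1, 1))
  expect_error(extract_landmarks(sk), "carina not found")
})

test_that("mirroring the volume swaps the left and right landmarks", {
  s <- small_phantom_clean()
  mask <- region_grow(s$ct, select_seed(s$ct))
  lm <- extract_landmarks(skeletonize(mask))
  d <- dim(s$ct$data)
  flipped <- ct_volume(s$ct$data[, , d[3]:1], s$ct$spacing_mm)
  mask_f <- region_grow(flipped, select_seed(flipped))
  lm_f <- extract_landmarks(skeletonize(mask_f))
  mirror_x <- function(p) c(p[1], p[2], d[3] + 1L - p[3])
  expect_equal(lm_f$left, mirror_x(lm$right), tolerance = 0)
  expect_equal(lm_f$right, mirror_x(lm$left), tolerance = 0)
})

test_that("landmark extraction is translation-equivariant", {
  s <- small_phantom_clean()
  lm <- extract_landmarks(skeletonize(region_grow(s$ct, select_seed(s$ct))))
  d <- dim(s$ct$data)
  shift <- 8L
  shifted <- array(-1000, d)
  shifted[, , (shift + 1):d[3]] <- s$ct$data[, , 1:(d[3] - shift)]
  vol2 <- ct_volume(shifted, s$ct$spacing_mm)
  lm2 <- extract_landmarks(skeletonize(region_grow(vol2, select_seed(vol2))))
  for (nm in c("root", "center", "left", "right"))
    expect_equal(lm2[[nm]], lm[[nm]] + c(0L, 0L, shift))
})

test_that("landmarks of 20 random phantoms stay inside the dilated airway", {
  offs <- lungraph:::sphere_offsets(2.5, c(1, 1, 1))   # 2-voxel dilation ball
  for (seed in 1:20) {
    s <- generate_phantom(small_spec(seed = 100 + seed))
    lm <- structure(s$landmarks_truth, class = "landmark_set")
    seg <- tryCatch(segment_airway(s$ct), error = function(e) e)
    expect_false(inherits(seg, "error"),
                 info = sprintf("segmentation failed for seed %d", seed))
    if (inherits(seg, "error")) next
    for (nm in c("root", "center", "left", "right")) {
      p <- seg$landmarks[[nm]]
      near <- sweep(offs, 2, p, "+")
      d <- dim(s$airway_truth)
      ok <- near[, 1] >= 1 & near[, 1] <= d[1] & near[, 2] >= 1 &
        near[, 2] <= d[2] & near[, 3] >= 1 & near[, 3] <= d[3]
      expect_true(any(s$airway_truth[near[ok, , drop = FALSE]]),
                  info = sprintf("%s landmark off-airway for seed %d", nm, seed))
    }
  }
})

test_that("landmark JSON round trip preserves 0-based coordinates", {
  lm <- structure(list(root = c(1L, 48L, 48L), center = c(33L, 48L, 48L),
                       left = c(59L, 48L, 66L), right = c(60L, 48L, 31L)),
                  class = "landmark_set")
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(j$root), lm$root - 1L)
  back <- read_landmarks(path)
  expect_identical(back$center, lm$center)
})
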