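# Synthetic chest-CT phantom: an air-filled Y-shaped airway tree inside two
# lung ellipsoids partitioned into five lobes, wrapped in a soft-tissue
# thorax, with one spherical tumor and exponential survival times whose
# hazard is driven by the planted tumor diameter.

# Intensity palette (HU, before noise).  Only the ordering matters:
# air << parenchyma < tumor/soft tissue.
HU_AIR    <- -1000
HU_LUNG   <- -800
HU_TISSUE <- 0
HU_TUMOR  <- 40

LOBE_NAMES <- c("LUL", "LLL", "RUL", "RML", "RLL")   # label values 1..5

#' Phantom specification
#'
#' Describes one synthetic thorax.  Geometry is stated in mm and scales with
#' the volume extent; defaults emulate a half-scale thorax that keeps every
#' stage fast on one CPU.
#'
#' @param volume_shape voxels per axis (z, y, x), all >= 64.
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @param trachea list: `radius_mm`, `length_mm` (entry at the superior face
#'   to the carina), `entry_frac` (y, x position as fraction of extent).
#' @param branch_angles_deg main-bronchus angles from vertical,
#'   `c(left =, right =)`.
#' @param bronchus list: `radius_mm`, `length_mm`.
#' @param lobe_layout z-split fractions of each lung's height:
#'   `left` (LUL/LLL boundary), `right` (RUL/RML and RML/RLL boundaries).
#' @param tumor list: `lobe` (1..5), `diameter_mm`, `intensity_offset_hu`.
#' @param extra_generations extra airway generations beyond the two main
#'   bronchi (0 = plain Y-tree).
#' @param noise_sd_hu Gaussian noise SD in HU added to the CT (not to the
#'   ground-truth masks).
#' @param seed RNG seed for noise and tumor placement.
#' @return a validated `phantom_spec` object.
#' @export
phantom_spec <- function(volume_shape = c(128, 128, 128),
                         spacing_mm = c(1.25, 1.25, 1.25),
                         trachea = list(radius_mm = 4, length_mm = 40,
                                        entry_frac = c(0.5, 0.5)),
                         branch_angles_deg = c(left = 35, right = 30),
                         bronchus = list(radius_mm = 3, length_mm = 40),
                         lobe_layout = list(left = 0.45, right = c(0.33, 0.62)),
                         tumor = list(lobe = 1L, diameter_mm = 20,
                                      intensity_offset_hu = 0),
                         extra_generations = 0L,
                         noise_sd_hu = 20,
                         seed = 1L) {
  spec <- structure(list(volume_shape = as.integer(volume_shape),
                         spacing_mm = as.numeric(spacing_mm),
                         trachea = trachea,
                         branch_angles_deg = branch_angles_deg,
                         bronchus = bronchus,
                         lobe_layout = lobe_layout,
                         tumor = tumor,
                         extra_generations = as.integer(extra_generations),
                         noise_sd_hu = noise_sd_hu,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$volume_shape) == 3, length(spec$spacing_mm) == 3)
  if (any(spec$volume_shape < 64))
    stop("volume_shape must be >= 64 voxels on every axis")
  if (any(spec$spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (spec$trachea$radius_mm / max(spec$spacing_mm) < 2)
    stop("trachea radius must span at least 2 voxels at the stated spacing")
  if (!spec$tumor$lobe %in% 1:5) stop("tumor lobe must be in 1..5")
  if (spec$tumor$diameter_mm <= 0) stop("tumor diameter must be positive")
  if (spec$noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  invisible(spec)
}

# Integer voxel offsets (z,y,x) of a sphere of radius r_mm at a spacing.
sphere_offsets <- function(r_mm, spacing_mm) {
  n <- floor(r_mm / spacing_mm)
  g <- expand.grid(z = -n[1]:n[1], y = -n[2]:n[2], x = -n[3]:n[3])
  d2 <- (g$z * spacing_mm[1])^2 + (g$y * spacing_mm[2])^2 + (g$x * spacing_mm[3])^2
  as.matrix(g[d2 <= r_mm^2, , drop = FALSE])
}

# Set arr[center + offsets] <- TRUE for in-bounds voxels; center 1-based (z,y,x).
stamp <- function(arr, center, offsets) {
  d <- dim(arr)
  z <- center[1] + offsets[, 1]; y <- center[2] + offsets[, 2]; x <- center[3] + offsets[, 3]
  ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
  arr[cbind(z[ok], y[ok], x[ok])] <- TRUE
  arr
}

# Capsule (tube with round caps) from p0 to p1 (mm), radius r_mm.
# Computes all covered linear indices at once: per-step array writes would
# copy the full volume each time.
stamp_capsule <- function(arr, p0_mm, p1_mm, r_mm, spacing_mm) {
  offs <- sphere_offsets(r_mm, spacing_mm)
  len <- sqrt(sum((p1_mm - p0_mm)^2))
  n_steps <- max(2L, ceiling(len / (min(spacing_mm) / 2)))
  ts <- seq(0, 1, length.out = n_steps)
  centers <- cbind(p0_mm[1] + ts * (p1_mm[1] - p0_mm[1]),
                   p0_mm[2] + ts * (p1_mm[2] - p0_mm[2]),
                   p0_mm[3] + ts * (p1_mm[3] - p0_mm[3]))
  centers <- round(sweep(centers, 2, spacing_mm, "/")) + 1
  z <- outer(centers[, 1], offs[, 1], "+")
  y <- outer(centers[, 2], offs[, 2], "+")
  x <- outer(centers[, 3], offs[, 3], "+")
  d <- dim(arr)
  ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
  arr[(x[ok] - 1) * d[1] * d[2] + (y[ok] - 1) * d[1] + z[ok]] <- TRUE
  arr
}

ellipsoid_mask <- function(dims, spacing, center_mm, semi_mm) {
  zc <- ((seq_len(dims[1]) - 1) * spacing[1] - center_mm[1])^2 / semi_mm[1]^2
  yc <- ((seq_len(dims[2]) - 1) * spacing[2] - center_mm[2])^2 / semi_mm[2]^2
  xc <- ((seq_len(dims[3]) - 1) * spacing[3] - center_mm[3])^2 / semi_mm[3]^2
  outer(zc, outer(yc, xc, "+"), "+") <= 1
}

# Deterministic geometric layout shared by the CT assembly and the ground
# truth (landmarks, analytic airway volume).
phantom_geometry <- function(spec) {
  ext <- spec$volume_shape * spec$spacing_mm      # extent in mm, (z, y, x)
  cy <- ext[2] / 2; cx <- ext[3] / 2
  entry <- spec$trachea$entry_frac
  t_yx <- c(ext[2] * entry[1], ext[3] * entry[2])
  carina <- c(spec$trachea$length_mm, t_yx[1], t_yx[2])
  a_l <- spec$branch_angles_deg[["left"]] * pi / 180
  a_r <- spec$branch_angles_deg[["right"]] * pi / 180
  bl <- spec$bronchus$length_mm
  left_end  <- carina + bl * c(cos(a_l), 0,  sin(a_l))   # patient-left: +x
  right_end <- carina + bl * c(cos(a_r), 0, -sin(a_r))
  list(ext = ext,
       body_center = c(NA, cy, cx),
       body_semi = c(NA, 0.44 * ext[2], 0.46 * ext[3]),
       lung_center_z = 0.52 * ext[1],
       lung_semi = c(0.40 * ext[1], 0.30 * ext[2], 0.165 * ext[3]),
       lung_off_x = 0.21 * ext[3],
       trachea_top = c(0, t_yx[1], t_yx[2]),
       carina = carina, left_end = left_end, right_end = right_end)
}

#' Generate one synthetic thorax phantom
#'
#' Deterministic for a fixed spec (the seed is part of the spec).  The CT is
#' assembled as: ambient air (-1000 HU) around a soft-tissue thorax (0 HU)
#' containing two lung ellipsoids (-800 HU), a spherical tumor
#' (+40 HU + configured offset) inside its host lobe, and the carved airway
#' lumen (-1000 HU); Gaussian noise is added last.
#'
#' @param spec a [phantom_spec].
#' @return a `phantom_sample`: `ct` ([ct_volume]), `airway_truth` (logical
#'   array), `lobe_labels` (integer array, 0 background / 1..5 lobes),
#'   `tumor_annotation` (`bbox` 0-based half-open + `lobes`),
#'   `landmarks_truth` (designed root/center/left/right, 1-based voxels),
#'   `survival` (filled by [generate_cohort]), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    d <- spec$volume_shape; sp <- spec$spacing_mm
    geo <- phantom_geometry(spec)

    # thorax: elliptical cylinder spanning all z (the "neck" embeds the trachea)
    yc <- ((seq_len(d[2]) - 1) * sp[2] - geo$body_center[2])^2 / geo$body_semi[2]^2
    xc <- ((seq_len(d[3]) - 1) * sp[3] - geo$body_center[3])^2 / geo$body_semi[3]^2
    body2d <- outer(yc, xc, "+") <= 1
    body <- array(rep(body2d, each = d[1]), d)

    lung_l <- ellipsoid_mask(d, sp,
      c(geo$lung_center_z, geo$body_center[2], geo$body_center[3] + geo$lung_off_x),
      geo$lung_semi)
    lung_r <- ellipsoid_mask(d, sp,
      c(geo$lung_center_z, geo$body_center[2], geo$body_center[3] - geo$lung_off_x),
      geo$lung_semi)

    # lobe partition by z within each lung
    zmm <- (seq_len(d[1]) - 1) * sp[1]
    z_top <- geo$lung_center_z - geo$lung_semi[1]
    h <- 2 * geo$lung_semi[1]
    zl <- z_top + spec$lobe_layout$left * h
    zr <- z_top + spec$lobe_layout$right * h
    zarr <- array(rep(zmm, times = d[2] * d[3]), d)
    lobes <- array(0L, d)
    lobes[lung_l & zarr <  zl] <- 1L   # LUL
    lobes[lung_l & zarr >= zl] <- 2L   # LLL
    lobes[lung_r & zarr <  zr[1]] <- 3L                    # RUL
    lobes[lung_r & zarr >= zr[1] & zarr < zr[2]] <- 4L     # RML
    lobes[lung_r & zarr >= zr[2]] <- 5L                    # RLL

    # airway tree
    airway <- array(FALSE, d)
    airway <- stamp_capsule(airway, geo$trachea_top, geo$carina,
                            spec$trachea$radius_mm, sp)
    airway <- stamp_capsule(airway, geo$carina, geo$left_end,
                            spec$bronchus$radius_mm, sp)
    airway <- stamp_capsule(airway, geo$carina, geo$right_end,
                            spec$bronchus$radius_mm, sp)
    if (spec$extra_generations > 0) {
      r2 <- spec$bronchus$radius_mm * 0.7
      l2 <- spec$bronchus$length_mm * 0.45
      for (end in list(geo$left_end, geo$right_end)) {
        for (sgn in c(-1, 1)) {
          child <- end + l2 * c(cos(pi / 5), sgn * sin(pi / 5), 0)
          airway <- stamp_capsule(airway, end, child, r2, sp)
        }
      }
    }

    # tumor placement: near the host lobe's centroid, fully inside the lobe,
    # clear of the airway
    r_mm <- spec$tumor$diameter_mm / 2
    offs <- sphere_offsets(r_mm, sp)
    offs_clear <- sphere_offsets(r_mm + 2 * min(sp), sp)
    lobe_vox <- which(lobes == spec$tumor$lobe, arr.ind = TRUE)
    if (nrow(lobe_vox) == 0)
      stop(sprintf("lobe %s is empty in this phantom", LOBE_NAMES[spec$tumor$lobe]))
    centroid <- colMeans(lobe_vox)
    n_cand <- min(nrow(lobe_vox), 400L)
    cand <- lobe_vox[sample.int(nrow(lobe_vox), n_cand), , drop = FALSE]
    ord <- order(colSums((t(cand) - centroid)^2))
    cand <- rbind(round(centroid), cand[ord, , drop = FALSE])
    lobe_ok <- lobes == spec$tumor$lobe
    tumor_center <- NULL
    for (i in seq_len(nrow(cand))) {
      ctr <- as.integer(cand[i, ])
      z <- ctr[1] + offs[, 1]; y <- ctr[2] + offs[, 2]; x <- ctr[3] + offs[, 3]
      if (any(z < 1 | z > d[1] | y < 1 | y > d[2] | x < 1 | x > d[3])) next
      if (!all(lobe_ok[cbind(z, y, x)])) next
      zc <- ctr[1] + offs_clear[, 1]; ycl <- ctr[2] + offs_clear[, 2]; xcl <- ctr[3] + offs_clear[, 3]
      keep <- zc >= 1 & zc <= d[1] & ycl >= 1 & ycl <= d[2] & xcl >= 1 & xcl <= d[3]
      if (any(airway[cbind(zc[keep], ycl[keep], xcl[keep])])) next
      tumor_center <- ctr
      break
    }
    if (is.null(tumor_center))
      stop(sprintf("tumor of %g mm does not fit in lobe %s",
                   spec$tumor$diameter_mm, LOBE_NAMES[spec$tumor$lobe]))
    tumor <- array(FALSE, d)
    tumor <- stamp(tumor, tumor_center, offs)

    # assemble CT
    ct <- array(HU_AIR, d)
    ct[body] <- HU_TISSUE
    ct[lung_l | lung_r] <- HU_LUNG
    ct[tumor] <- HU_TUMOR + spec$tumor$intensity_offset_hu
    ct[airway] <- HU_AIR
    if (spec$noise_sd_hu > 0)
      ct <- ct + array(rnorm(prod(d), 0, spec$noise_sd_hu), d)

    bb <- mask_bbox(tumor)
    margin <- 2L
    bb$min <- pmax(bb$min - margin, 0L)
    bb$max <- pmin(bb$max + margin, d)
    ann <- list(bbox = bb, lobes = as.integer(spec$tumor$lobe))

    to_vox <- function(p_mm) pmin(pmax(as.integer(round(p_mm / sp)) + 1L, 1L), d)
    landmarks <- list(root = to_vox(geo$trachea_top + c(sp[1] / 2, 0, 0)),
                      center = to_vox(geo$carina),
                      left = to_vox(geo$left_end),
                      right = to_vox(geo$right_end))

    structure(list(ct = ct_volume(ct, sp),
                   airway_truth = airway,
                   lobe_labels = lobes,
                   tumor_annotation = ann,
                   landmarks_truth = landmarks,
                   survival = NULL,
                   spec = spec),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s voxels; airway %d vox; tumor %g mm in %s\n",
              paste(dim(x$ct$data), collapse = "x"), sum(x$airway_truth),
              x$spec$tumor$diameter_mm, LOBE_NAMES[x$spec$tumor$lobe]))
  invisible(x)
}

# Analytic volume (mm^3) of the designed airway tree, for construction checks.
airway_design_volume <- function(spec) {
  geo <- phantom_geometry(spec)
  lt <- spec$trachea$length_mm
  lb <- spec$bronchus$length_mm
  pi * spec$trachea$radius_mm^2 * lt + 2 * pi * spec$bronchus$radius_mm^2 * lb
}

# Empirical per-lobe tumor-diameter capacity (mm) for the default geometry,
# conservative; generate_phantom still errors if a placement fails.
LOBE_CAPACITY_FRAC <- c(LUL = 0.20, LLL = 0.26, RUL = 0.18, RML = 0.20, RLL = 0.20)

#' Cohort specification for the phantom generator
#'
#' Survival is exponential: `T ~ Exp(h0 * exp(beta_size * diameter_cm))`
#' with administrative censoring at `censor_horizon_months`.  Recurrence
#' uses half the death hazard, so RFS = min(recurrence, death) time.
#'
#' @param n_patients cohort size, >= 2.
#' @param baseline_hazard events per month for a (hypothetical) 0-cm tumor.
#' @param beta_size log-hazard per cm of tumor diameter (planted effect).
#' @param censor_horizon_months administrative censoring time, > 60 so the
#'   5-year label is always defined.
#' @param diameter_range_mm tumor diameters are drawn uniformly here.
#' @param lobe_probs sampling weights for the host lobe (upper-lobe
#'   predominance, as in real cohorts); a draw that exceeds the lobe's
#'   geometric capacity is deterministically reassigned to the
#'   largest-capacity lobe.
#' @param volume_shape,spacing_mm,noise_sd_hu forwarded to each patient's
#'   [phantom_spec].
#' @param seed RNG seed; every patient gets a derived child seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients,
                        baseline_hazard = 0.0018,
                        beta_size = log(2),
                        censor_horizon_months = 84,
                        diameter_range_mm = c(8, 40),
                        lobe_probs = c(LUL = 0.25, LLL = 0.12, RUL = 0.33,
                                       RML = 0.08, RLL = 0.22),
                        volume_shape = c(128, 128, 128),
                        spacing_mm = c(1.25, 1.25, 1.25),
                        noise_sd_hu = 20,
                        seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_horizon_months <= 60)
    stop("censor_horizon_months must exceed 60 so the 5-year label is defined")
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard,
                 beta_size = beta_size,
                 censor_horizon_months = censor_horizon_months,
                 diameter_range_mm = diameter_range_mm,
                 lobe_probs = lobe_probs,
                 volume_shape = as.integer(volume_shape),
                 spacing_mm = spacing_mm,
                 noise_sd_hu = noise_sd_hu,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-patient tumor geometry and survival outcomes and returns the
#' cohort table plus one [phantom_spec] per patient.  CT volumes are
#' materialized on demand with [cohort_sample] (a 400-patient cohort of
#' in-memory volumes would need gigabytes).
#'
#' The binary 5-year label is 1 for death within 60 months, 0 for survival
#' beyond 60 months, and NA for patients censored alive before 60 months
#' (excluded from classification, retained for KM/Cox); with the default
#' administrative horizon > 60 months no label is NA.
#'
#' @param cs a [cohort_spec].
#' @return a `phantom_cohort`: `table` (data.frame with id, os/rfs columns,
#'   label_5yr and the true tumor covariates) and `specs` (list of
#'   [phantom_spec]).
#' @export
generate_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  n <- cs$n_patients
  ext_mm <- min(cs$volume_shape * cs$spacing_mm)
  capacity <- LOBE_CAPACITY_FRAC * ext_mm
  with_seed(cs$seed, {
    diam <- runif(n, cs$diameter_range_mm[1], cs$diameter_range_mm[2])
    lobe <- sample(1:5, n, replace = TRUE, prob = cs$lobe_probs)
    for (i in seq_len(n)) {
      if (diam[i] > capacity[lobe[i]]) lobe[i] <- which.max(capacity)
    }
    rate <- cs$baseline_hazard * exp(cs$beta_size * diam / 10)
    t_death <- rexp(n, rate)
    t_rec <- rexp(n, 0.5 * rate)
    hor <- cs$censor_horizon_months
    os_event <- as.integer(t_death <= hor)
    os_months <- pmin(t_death, hor)
    t_rfs <- pmin(t_death, t_rec)
    rfs_event <- as.integer(t_rfs <= hor)
    rfs_months <- pmin(t_rfs, hor)
    label <- ifelse(os_months > 60, 0L, ifelse(os_event == 1, 1L, NA_integer_))
    tab <- data.frame(id = sprintf("P%04d", seq_len(n)),
                      os_months = os_months, os_event = os_event,
                      rfs_months = rfs_months, rfs_event = rfs_event,
                      label_5yr = label,
                      tumor_lobe = lobe,
                      tumor_diameter_mm = diam,
                      stringsAsFactors = FALSE)
    specs <- lapply(seq_len(n), function(i) {
      phantom_spec(volume_shape = cs$volume_shape, spacing_mm = cs$spacing_mm,
                   tumor = list(lobe = lobe[i], diameter_mm = diam[i],
                                intensity_offset_hu = 0),
                   noise_sd_hu = cs$noise_sd_hu,
                   seed = child_seed(cs$seed, i))
    })
    structure(list(table = tab, specs = specs, cohort_spec = cs),
              class = "phantom_cohort")
  })
}

#' Materialize one patient of a phantom cohort
#'
#' @param cohort a `phantom_cohort` from [generate_cohort].
#' @param i patient index (or id string).
#' @return the patient's `phantom_sample`, with `survival` filled in.
#' @export
cohort_sample <- function(cohort, i) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (is.character(i)) i <- match(i, cohort$table$id)
  s <- generate_phantom(cohort$specs[[i]])
  s$survival <- list(id = cohort$table$id[i],
                     time_months = cohort$table$os_months[i],
                     event = cohort$table$os_event[i],
                     label_5yr = cohort$table$label_5yr[i])
  s
}

#' Write a phantom sample to disk
#'
#' NIfTI for the CT, airway truth and lobe labels; JSON (0-based, half-open
#' bounding box) for the tumor annotation.
#'
#' @param sample a `phantom_sample`.
#' @param dir output directory (created if missing).
#' @param id file stem, e.g. the patient id.
#' @return the directory, invisibly.
#' @export
write_phantom_sample <- function(sample, dir, id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- sample$ct$spacing_mm
  write_nifti(sample$ct, file.path(dir, paste0(id, "_ct.nii.gz")))
  write_nifti(array(as.integer(sample$airway_truth), dim(sample$airway_truth)),
              file.path(dir, paste0(id, "_airway.nii.gz")),
              spacing_mm = sp, datatype = "uint8")
  write_nifti(sample$lobe_labels, file.path(dir, paste0(id, "_lobes.nii.gz")),
              spacing_mm = sp, datatype = "uint8")
  ann <- sample$tumor_annotation
  jsonlite::write_json(list(bbox_zyx_min = ann$bbox$min,
                            bbox_zyx_max = ann$bbox$max,
                            lobes = ann$lobes),
                       file.path(dir, paste0(id, "_tumor.json")),
                       auto_unbox = FALSE)
  invisible(dir)
}

#' Write a cohort table as CSV
#'
#' Columns: id, os_months, os_event, rfs_months, rfs_event, label_5yr (plus
#' the true tumor covariates); numeric columns at full precision.
#'
#' @param cohort a `phantom_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  tab <- cohort$table
  num <- vapply(tab, is.numeric, logical(1)) & !vapply(tab, is.integer, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table]
#' @param path CSV path.
#' @return a data.frame.
#' @export
read_cohort_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
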