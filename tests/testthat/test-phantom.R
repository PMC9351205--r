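# Phantom generator: determinism, construction invariants, the analytic
# airway volume, and the planted survival signal.

fast_spec <- function(tumor = list(lobe = 2L, diameter_mm = 16,
                                   intensity_offset_hu = 0), ...) {
  phantom_spec(volume_shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
               tumor = tumor, ...)
}

test_that("same spec and seed give voxel-identical phantoms", {
  a <- generate_phantom(fast_spec(seed = 11))
  b <- generate_phantom(fast_spec(seed = 11))
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$lobe_labels, b$lobe_labels)
  expect_identical(a$tumor_annotation, b$tumor_annotation)
})

test_that("noise-free construction honors the intensity palette", {
  s <- generate_phantom(fast_spec(seed = 2, noise_sd_hu = 0))
  expect_true(all(s$ct$data[s$airway_truth] == -1000))
  lungs <- s$lobe_labels > 0
  tum <- s$ct$data == 40
  expect_true(any(tum))
  expect_true(all(s$ct$data[lungs & !s$airway_truth & !tum] == -800))
})

test_that("phantom structural invariants hold", {
  s <- small_phantom()
  d <- dim(s$ct$data)
  # airway lumen stays air-valued under noise
  expect_true(all(s$ct$data[s$airway_truth] <= -900))
  # one 26-connected airway component
  lab <- lungraph:::`.cc_label26`(as.logical(s$airway_truth), d)
  expect_identical(attr(lab, "n_components"), 1L)
  # lobes mutually exclusive by construction of a label map; all five present
  expect_setequal(sort(unique(as.vector(s$lobe_labels[s$lobe_labels > 0]))), 1:5)
  # tumor bbox inside the volume
  bb <- s$tumor_annotation$bbox
  expect_true(all(bb$min >= 0) && all(bb$max <= d))
})

test_that("airway mask volume matches the analytic tube volume within 20%", {
  spec <- phantom_spec(volume_shape = c(96, 96, 96), spacing_mm = c(1, 1, 1),
                       tumor = list(lobe = 2L, diameter_mm = 14,
                                    intensity_offset_hu = 0),
                       noise_sd_hu = 0, seed = 5)
  s <- generate_phantom(spec)
  measured <- sum(s$airway_truth) * prod(spec$spacing_mm)
  expect_lt(abs(measured - airway_design_volume(spec)) / airway_design_volume(spec),
            0.20)
})

test_that("an oversized tumor fails with the lobe named", {
  expect_error(generate_phantom(fast_spec(tumor = list(
    lobe = 4L, diameter_mm = 60, intensity_offset_hu = 0))),
    "does not fit in lobe RML")
})

test_that("cohort generation is deterministic and respects the horizon", {
  cs <- cohort_spec(n_patients = 50, seed = 9)
  a <- generate_cohort(cs); b <- generate_cohort(cs)
  expect_identical(a$table, b$table)
  expect_true(all(a$table$os_months <= cs$censor_horizon_months))
  expect_true(all(a$table$rfs_months <= a$table$os_months + 1e-12))
  # label consistency: event implies time <= horizon; labels defined (horizon > 60)
  expect_true(all(a$table$os_months[a$table$os_event == 1] <= cs$censor_horizon_months))
  expect_false(anyNA(a$table$label_5yr))
  expect_identical(a$table$label_5yr,
                   ifelse(a$table$os_months > 60, 0L,
                          ifelse(a$table$os_event == 1, 1L, NA_integer_)))
  expect_error(cohort_spec(n_patients = 1), ">= 2")
  expect_error(cohort_spec(n_patients = 5, censor_horizon_months = 48), "exceed 60")
})

test_that("cohort CSV round trip is lossless", {
  cohort <- generate_cohort(cohort_spec(n_patients = 12, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(cohort, path)
  back <- read_cohort_table(path)
  expect_equal(back$os_months, cohort$table$os_months)
  expect_identical(back$os_event, cohort$table$os_event)
  expect_identical(back$id, cohort$table$id)
})

test_that("beta_size = 0 removes the size-survival association", {
  cohort <- generate_cohort(cohort_spec(n_patients = 300, beta_size = 0, seed = 21))
  tab <- cohort$table
  grp <- factor(ifelse(tab$tumor_diameter_mm > median(tab$tumor_diameter_mm),
                       "large", "small"))
  rec <- survival_records(tab$id, tab$os_months, tab$os_event)
  lr <- log_rank(grp, rec)
  expect_gt(lr$p, 0.001)
  fit <- cox_hr(as.integer(grp == "large"), rec)
  expect_true(fit$ci[1] < 1 && fit$ci[2] > 1)
})

test_that("planted effect is recovered by Cox on the true diameter", {
  cohort <- generate_cohort(cohort_spec(n_patients = 400, seed = 17))
  tab <- cohort$table
  fit <- survival::coxph(survival::Surv(os_months, os_event) ~ I(tumor_diameter_mm / 10),
                         data = tab)
  hr <- exp(coef(fit))
  expect_gt(hr, 1.6); expect_lt(hr, 2.5)
})

test_that("5-year label is predictable from the true diameter (AUC > 0.65)", {
  cohort <- generate_cohort(cohort_spec(n_patients = 400, seed = 17))
  tab <- cohort$table[!is.na(cohort$table$label_5yr), ]
  m <- glm(label_5yr ~ tumor_diameter_mm, data = tab, family = "binomial")
  auc <- roc_auc(predict(m, type = "response"), tab$label_5yr, conf = FALSE)$auc
  expect_gt(auc, 0.65)
})

test_that("phantom samples write NIfTI + JSON artifacts", {
  s <- generate_phantom(fast_spec(seed = 8))
  dir <- withr::local_tempdir()
  write_phantom_sample(s, dir, "p1")
  expect_true(all(file.exists(file.path(dir, c("p1_ct.nii.gz", "p1_airway.nii.gz",
                                               "p1_lobes.nii.gz", "p1_tumor.json")))))
  back <- read_nifti(file.path(dir, "p1_lobes.nii.gz"))
  expect_equal(back$data, s$lobe_labels + 0)
  ann <- jsonlite::read_json(file.path(dir, "p1_tumor.json"), simplifyVector = TRUE)
  expect_identical(as.integer(ann$bbox_zyx_min), s$tumor_annotation$bbox$min)
  expect_identical(as.integer(ann$lobes), s$tumor_annotation$lobes)
})
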