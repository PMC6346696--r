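# Digital phantom generation: rasterization, system blur, noise,
# counts branch, cohort generator.

make_test_spec <- function(lesions = NULL, fov = c(96, 96, 96), bg = 5, ...) {
  phantom_spec(fov_mm = fov, lesions = lesions, background = bg, ...)
}

test_that("rasterization matches brute-force center-membership counts", {
  les <- data.frame(x_mm = 48, y_mm = 48, z_mm = 48, radius_mm = 9.6,
                    suv = 30, site = "spine", class = "benign")
  spec <- make_test_spec(les)
  out <- rasterize_phantom(spec)
  # brute force on the SPECT grid
  xc <- (1:20 - 0.5) * 4.8
  d2 <- outer(outer((xc - 48)^2, (xc - 48)^2, `+`), (xc - 48)^2, `+`)
  expect_equal(out$truth$lesions$n_vox_spect, sum(d2 <= 9.6^2))
  cps <- out$truth$conc_per_suv[["spect"]]
  expect_equal(sum(out$spect$values == 30 * cps), sum(d2 <= 9.6^2))
  # empty lesion list -> uniform background
  out0 <- rasterize_phantom(make_test_spec())
  expect_equal(length(unique(as.vector(out0$spect$values))), 1L)
  # uptake ratio 1: identical SUV patterns up to grid resampling
  spec1 <- make_test_spec(les, uptake_ratio = 1)
  out1 <- rasterize_phantom(spec1)
  expect_equal(max(out1$pet$values) / out1$truth$conc_per_suv[["pet"]],
               max(out1$spect$values) / out1$truth$conc_per_suv[["spect"]])
  # lesion outside the field of view is rejected
  bad <- data.frame(x_mm = 2, y_mm = 48, z_mm = 48, radius_mm = 9.6,
                    suv = 30, site = "spine", class = "benign")
  expect_suvpair_error(make_test_spec(bad), "suvpair_invalid_argument")
})

test_that("system model: identity at fwhm 0, flat interiors, monotone peak erosion", {
  vol <- make_sphere_volume(c(21, 21, 21), c(4.8, 4.8, 4.8), radius_mm = 15)
  expect_equal(apply_system_model(vol, 0)$values, vol$values)
  # uniform volume far from edges: interior unchanged by normalized kernel
  u <- quant_volume(array(7, c(25, 25, 25)), c(4, 4, 4), unit = "SUV")
  bu <- apply_system_model(u, 10)
  expect_equal(bu$values[13, 13, 13], 7, tolerance = 1e-12)
  # hot-sphere maximum is non-increasing in fwhm
  maxes <- sapply(c(0, 4, 8, 12, 16), function(f) {
    max(apply_system_model(vol, f)$values)
  })
  expect_true(all(diff(maxes) <= 1e-12))
  expect_suvpair_error(apply_system_model(vol, -1), "suvpair_invalid_argument")
})

test_that("blur conserves total activity away from borders", {
  les <- data.frame(x_mm = 120, y_mm = 120, z_mm = 120, radius_mm = 12,
                    suv = 40, site = "spine", class = "benign")
  spec <- make_test_spec(les, fov = c(240, 240, 240), bg = 1)
  out <- rasterize_phantom(spec)
  # subtract background to isolate the lesion signal (background is flat and
  # conserved exactly in the interior)
  sig <- out$spect$values - min(out$spect$values)
  blurred <- apply_system_model(
    quant_volume(sig, out$spect$spacing, unit = "Bq_per_ml"), 12)
  expect_equal(sum(blurred$values) / sum(sig), 1, tolerance = 0.005)
})

test_that("noise is seeded, signal-scaled, and clipped at zero", {
  vol <- quant_volume(array(100, c(12, 12, 12)), c(4, 4, 4), unit = "SUV")
  n1 <- apply_system_model(vol, 0, "gaussian_scaled", 0.5, seed = 42)
  n2 <- apply_system_model(vol, 0, "gaussian_scaled", 0.5, seed = 42)
  n3 <- apply_system_model(vol, 0, "gaussian_scaled", 0.5, seed = 43)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_true(all(n1$values >= 0))
  expect_equal(sd(n1$values), 0.5 * sqrt(100), tolerance = 0.1)
})

test_that("counts branch is the exact inverse of calibration", {
  set.seed(151)
  conc <- quant_volume(array(runif(1000, 0, 5e4), c(10, 10, 10)),
                       c(4.8, 4.8, 4.8), unit = "Bq_per_ml")
  cps <- to_counts_branch(conc, 0.107)
  back <- counts_to_concentration(cps, calibration_factor(0.107))
  expect_equal(back$values, conc$values, tolerance = 1e-12)
  # factor 1 with 1-ml voxels: same numbers, new unit tag
  conc1 <- quant_volume(array(2.5, c(3, 3, 3)), c(10, 10, 10),
                        unit = "Bq_per_ml")
  cps1 <- to_counts_branch(conc1, 1)
  expect_equal(cps1$values, conc1$values / 1000)  # kBq vs Bq
  expect_equal(cps1$unit, "cps")
})

test_that("cohort generation is deterministic in the seed", {
  c1 <- make_paired_cohort(n_lesions = 8, seed = 5, psf_fwhm = c(spect = 0, pet = 0),
                           noise_model = "none")
  c2 <- make_paired_cohort(n_lesions = 8, seed = 5, psf_fwhm = c(spect = 0, pet = 0),
                           noise_model = "none")
  c3 <- make_paired_cohort(n_lesions = 8, seed = 6, psf_fwhm = c(spect = 0, pet = 0),
                           noise_model = "none")
  expect_identical(c1$seeds, c2$seeds)
  expect_identical(c1$truth$lesions, c2$truth$lesions)
  expect_identical(c1$spect_counts$values, c2$spect_counts$values)
  expect_false(identical(c1$truth$lesions$x_mm, c3$truth$lesions$x_mm))
})

test_that("zero-blur cohort: full pipeline recovers programmed SUVs and SUVRs", {
  coh <- make_paired_cohort(n_lesions = 12, seed = 3,
                            psf_fwhm = c(spect = 0, pet = 0),
                            noise_model = "none")
  spect_suv <- to_suv(
    counts_to_concentration(coh$spect_counts,
                            calibration_factor(coh$calibration_kBq_per_cps)),
    coh$acq_spect)
  pet_suv <- to_suv(coh$pet_conc, coh$acq_pet)
  res <- analyze_paired_lesions(spect_suv, pet_suv, coh$seeds, coh$bg_rois)
  paired <- pair_lesion_records(res$lesions)
  tr <- coh$truth$lesions
  m <- match(paired$lesion_id, tr$lesion_id)
  # programmed lesion SUV_mean and SUV_max recovered exactly
  expect_equal(paired$spect_suv_mean, tr$spect_suv[m], tolerance = 1e-12)
  expect_equal(paired$pet_suv_max, tr$pet_suv[m], tolerance = 1e-12)
  # SUVRs recovered exactly, and identical across modalities
  expect_equal(paired$spect_suvr_mean, tr$spect_suv[m] / tr$bg_suv_spect[m],
               tolerance = 1e-12)
  expect_equal(paired$pet_suvr_max, paired$spect_suvr_max, tolerance = 1e-12)
  # segmented volume within one voxel shell of truth for a ~2 cm^3 lesion
  mid <- which.min(abs(tr$volume_true_cm3[m] - 2))
  shell <- (tr$n_vox_pet[m][mid]^(2 / 3) * 6) * prod(c(3.65, 3.65, 3.27)) / 1000
  expect_lt(abs(paired$volume_cm3[mid] - tr$volume_true_cm3[m][mid]), shell)
})

test_that("partial-volume mechanism: SPECT blur depresses SPECT SUV_max more", {
  coh <- make_paired_cohort(n_lesions = 16, seed = 13, uptake_ratio = 1,
                            psf_fwhm = c(spect = 12, pet = 8),
                            noise_model = "none")
  spect_suv <- to_suv(
    counts_to_concentration(coh$spect_counts,
                            calibration_factor(coh$calibration_kBq_per_cps)),
    coh$acq_spect)
  pet_suv <- to_suv(coh$pet_conc, coh$acq_pet)
  res <- analyze_paired_lesions(spect_suv, pet_suv, coh$seeds, coh$bg_rois)
  paired <- pair_lesion_records(res$lesions)
  d <- 100 * (paired$pet_suv_max - paired$spect_suv_max) / paired$spect_suv_max
  # positive median at uptake ratio 1: pure partial-volume effect
  expect_gt(median(d), 0)
  # effect shrinks with lesion size
  big <- paired$volume_cm3 > median(paired$volume_cm3)
  expect_gt(median(d[!big]), median(d[big]))
})

test_that("cohort respects programmed site background ordering", {
  coh <- make_paired_cohort(n_lesions = 30, seed = 17,
                            psf_fwhm = c(spect = 0, pet = 0),
                            noise_model = "none")
  spect_suv <- to_suv(
    counts_to_concentration(coh$spect_counts,
                            calibration_factor(coh$calibration_kBq_per_cps)),
    coh$acq_spect)
  pet_suv <- to_suv(coh$pet_conc, coh$acq_pet)
  res <- analyze_paired_lesions(spect_suv, pet_suv, coh$seeds, coh$bg_rois)
  paired <- pair_lesion_records(res$lesions)
  tab <- site_background_summary(paired)
  if (all(c("spine", "skull") %in% tab$site)) {
    expect_gt(tab$spect_median[tab$site == "spine"],
              tab$spect_median[tab$site == "skull"])
  }
  # generated seed rows and ROI counts are complete
  expect_equal(nrow(coh$seeds), 2 * 30)
  expect_equal(nrow(coh$bg_rois), 7 * 30)
})
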