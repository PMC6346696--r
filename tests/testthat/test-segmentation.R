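# Threshold segmentation, volume matching, VOI bookkeeping.

test_that("segment_threshold matches voxel-scan oracle on a hot sphere", {
  vol <- make_sphere_volume()
  voi <- segment_threshold(vol, c(8, 8, 8), 15)
  expect_equal(nrow(voi$idx), sum(vol$values > 15))
  expect_setequal(voi_indices(voi, dim(vol$values)), which(vol$values > 15))
  expect_true(all(vol$values[voi_indices(voi, dim(vol$values))] > voi$threshold))
  # uniform volume: everything connected is selected
  u <- quant_volume(array(20, c(4, 4, 4)), c(4.8, 4.8, 4.8), unit = "SUV")
  expect_equal(nrow(segment_threshold(u, c(2, 2, 2), 15)$idx), 64)
})

test_that("thresholding is strictly greater-than", {
  vals <- array(5, c(5, 5, 5))
  vals[3, 3, 3] <- 15  # exactly at threshold
  vals[3, 3, 2] <- 16
  v <- quant_volume(vals, c(1, 1, 1), unit = "SUV")
  expect_suvpair_error(segment_threshold(v, c(3, 3, 3), 15),
                       "suvpair_empty_segmentation")
  voi <- segment_threshold(v, c(3, 3, 2), 15)
  expect_equal(nrow(voi$idx), 1L)
})

test_that("connectivity separates disjoint spheres; outside relabeling is irrelevant", {
  dimv <- c(24, 12, 12)
  sp <- c(4, 4, 4)
  vals <- array(2, dimv)
  vol_a <- make_sphere_volume(dimv, sp, center_mm = c(20, 24, 24),
                              radius_mm = 10, hot = 30, bg = 2)
  vol_b <- make_sphere_volume(dimv, sp, center_mm = c(76, 24, 24),
                              radius_mm = 10, hot = 25, bg = 2)
  vals <- pmax(vol_a$values, vol_b$values)
  v <- quant_volume(vals, sp, unit = "SUV")
  voi <- segment_threshold(v, c(5, 6, 6), 15)
  in_b <- vals == 25
  expect_false(any(in_b[voi_indices(voi, dimv)]))
  # relabeling voxels outside the seed's component leaves the VOI unchanged
  vals2 <- vals
  vals2[vals2 == 25] <- 99
  voi2 <- segment_threshold(quant_volume(vals2, sp, unit = "SUV"),
                            c(5, 6, 6), 15)
  expect_equal(voi2$idx, voi$idx)
})

test_that("segmented volume is non-increasing in the threshold", {
  set.seed(31)
  vol <- random_volume(c(14, 14, 14), levels = seq(2, 28, by = 2))
  # grow from the hottest voxel so every threshold below it is seedable
  seed <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
  vols <- sapply(seq(2, 26, by = 2), function(t) {
    nrow(segment_threshold(vol, seed, t)$idx)
  })
  expect_true(all(diff(vols) <= 0))
})

test_that("match_volume_threshold equals the exhaustive-threshold oracle", {
  set.seed(41)
  for (rep in 1:12) {
    vol <- random_volume(c(9, 9, 9), spacing = c(5, 5, 5),
                         levels = sample(seq(1, 40), 10))
    seed <- which(vol$values == max(vol$values), arr.ind = TRUE)[1, ]
    target <- runif(1, 0.5, 12)  # cm^3; voxel = 0.125 cm^3
    orc <- oracle_match_volume(vol, seed, target)
    got <- tryCatch(
      match_volume_threshold(vol, seed, target, max_mismatch = Inf),
      suvpair_matching_failure = function(e) e)
    expect_false(inherits(got, "error"))
    expect_equal(nrow(got$idx), orc$n)
    expect_equal(voi_indices(got, dim(vol$values)), orc$lin)
    expect_equal(got$mismatch, orc$err / target, tolerance = 1e-12)
  }
})

test_that("volume matching: fixed point, k-hottest cone, and failure carry mismatch", {
  vol <- make_sphere_volume()
  ref <- segment_threshold(vol, c(8, 8, 8), 15)
  m <- match_volume_threshold(vol, c(8, 8, 8), ref$volume_cm3)
  expect_equal(sort(voi_indices(m, dim(vol$values))),
               sort(voi_indices(ref, dim(vol$values))))
  expect_equal(m$mismatch, 0)
  # monotone cone of distinct values: the k hottest voxels are returned
  d <- c(6, 6, 6)
  vals <- array(0, d)
  vals[] <- rev(seq_len(prod(d)))  # distinct, hottest at [1,1,1]
  v <- quant_volume(vals, c(10, 10, 10), unit = "SUV")  # 1 cm3 voxels
  for (k in c(1, 7, 30)) {
    got <- match_volume_threshold(v, c(1, 1, 1), k)
    expect_equal(nrow(got$idx), k)
    expect_setequal(v$values[voi_indices(got, d)],
                    sort(vals, decreasing = TRUE)[1:k])
  }
  # unreachable target -> matching failure carrying best mismatch
  err <- tryCatch(match_volume_threshold(v, c(1, 1, 1), 1.5, max_mismatch = 0.1),
                  suvpair_matching_failure = function(e) e)
  expect_s3_class(err, "suvpair_matching_failure")
  expect_true(is.numeric(err$best_mismatch))
})

test_that("ties break toward the larger volume", {
  # plateau structure: achievable component sizes 1 and 3; target 2 is
  # equidistant -> the larger (size 3) must win
  vals <- array(0, c(7, 1, 1))
  vals[, 1, 1] <- c(0, 5, 10, 20, 10, 5, 0)
  v <- quant_volume(vals, c(10, 10, 10), unit = "SUV")  # 1 cm3 voxels
  got <- match_volume_threshold(v, c(4, 1, 1), 2, max_mismatch = 1)
  expect_equal(nrow(got$idx), 3L)
})

test_that("voi_volume is voxel count times voxel volume", {
  idx <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  voi <- lesion_voi(idx, c(4.8, 4.8, 4.8), c(4, 4, 4))
  expect_equal(voi_volume(voi), 8 * 110.592 / 1000)
  expect_equal(voi_volume(matrix(c(1, 1, 1), 1), c(10, 10, 10)), 1.0)
  # brute-force: sum of per-voxel volumes
  set.seed(3)
  vol <- random_volume(c(10, 10, 10), spacing = c(2.5, 3, 4))
  voi2 <- random_voi(vol, 25)
  expect_equal(voi_volume(voi2), sum(rep(prod(c(2.5, 3, 4)) / 1000, 25)))
})

test_that("seed CSV reader validates schema", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(lesion_id = "L1", modality = "PET", i = 3, j = 4, k = 5,
                       site = "spine", class = "benign",
                       threshold_override = NA),
            f, row.names = FALSE)
  df <- read_lesion_seeds(f)
  expect_equal(df$i, 3)
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(lesion_id = "L1", i = 1), f2, row.names = FALSE)
  expect_suvpair_error(read_lesion_seeds(f2), "suvpair_validation_error")
})

test_that("out-of-bounds seeds and empty VOIs error cleanly", {
  vol <- make_sphere_volume()
  expect_suvpair_error(segment_threshold(vol, c(99, 1, 1), 15),
                       "suvpair_invalid_argument")
  expect_suvpair_error(match_volume_threshold(vol, c(0, 1, 1), 1),
                       "suvpair_invalid_argument")
  expect_suvpair_error(lesion_voi(matrix(numeric(0), ncol = 3),
                                  c(1, 1, 1), c(5, 5, 5)),
                       "suvpair_empty_voi")
})
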