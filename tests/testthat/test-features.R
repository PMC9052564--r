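test_that("intensity statistics follow the moment definitions", {
  const <- intensity_features(rep(40, 50), rep(2L, 50), 2L)
  expect_equal(unname(const["stat_variance"]), 0)
  expect_equal(unname(const["ih_entropy"]), 0)
  expect_equal(unname(const["ih_uniformity"]), 1)
  sym <- intensity_features(c(1, 2, 3), c(1L, 2L, 3L), 3L)
  expect_equal(unname(sym["stat_mean"]), 2)
  expect_equal(unname(sym["stat_skewness"]), 0)
  set.seed(21)
  x <- rnorm(1000)
  f <- intensity_features(x, rep(1L, 1000), 1L)
  expect_gt(unname(f["stat_variance"]), 0.8)
  expect_lt(unname(f["stat_variance"]), 1.2)
  expect_equal(unname(f["stat_energy"]), sum(x^2))
})

test_that("shape features recover known geometry", {
  # digital sphere, radius 10 voxels, isotropic spacing
  co <- seq_len(25) - 13
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  sph <- roi_mask(array(r2 <= 100, dim = c(25, 25, 25)), c(1, 1, 1))
  fs <- shape_features(sph)
  expect_lt(abs(fs[["shape_elongation"]] - 1), 0.02)
  expect_lt(abs(fs[["shape_flatness"]] - 1), 0.02)
  expect_equal(fs[["shape_volume"]], sum(sph$voxels))
  expect_lt(abs(fs[["shape_max_diameter"]] - 20), 1.5)

  # solid ellipsoid with semi-axes (20, 10, 10) voxels
  cx <- (seq_len(45) - 23) / 20
  cy <- (seq_len(25) - 13) / 10
  e2 <- outer(outer(cx^2, cy^2, `+`), cy^2, `+`)
  ell <- roi_mask(array(e2 <= 1, dim = c(45, 25, 25)), c(1, 1, 1))
  fe <- shape_features(ell)
  expect_lt(abs(fe[["shape_elongation"]] - 0.5), 0.05)

  # anisotropic voxel-count volume convention
  m <- array(FALSE, dim = c(6, 6, 4)); m[2:4, 2:4, 2:3] <- TRUE
  fa <- shape_features(roi_mask(m, c(1, 1, 3)))
  expect_equal(fa[["shape_volume"]], sum(m) * 3)
  # single voxel: elongation 1 by convention
  s <- array(FALSE, dim = c(3, 3, 3)); s[2, 2, 2] <- TRUE
  expect_equal(shape_features(roi_mask(s, c(1, 1, 1)))[["shape_elongation"]], 1)
})

test_that("the default catalogue has 1150 uniquely named features incl. the signature", {
  cat_df <- feature_catalogue()
  expect_equal(nrow(cat_df), 1150)
  expect_false(anyDuplicated(cat_df$name) > 0)
  expect_true(all(c("LHL_glszm_large_zone_emphasis",
                    "original_shape_elongation",
                    "HHH_ih_mean",
                    "HLL_glrlm_grey_level_variance",
                    "HHH_glcm_cluster_tendency") %in% cat_df$name))
  expect_equal(sum(cat_df$family == "shape"), 16)
  expect_equal(sum(cat_df$channel == "HHH"), 126)
})

test_that("extract_features is deterministic, complete and finite", {
  cases <- fixture("cohort_s3", small_case(seed = 3, n_cases = 30))
  cs <- cases[[1]]
  f1 <- extract_features(cs$volume, cs$mask)
  f2 <- extract_features(cs$volume, cs$mask)
  expect_identical(f1, f2)
  expect_length(f1, 1150)
  expect_identical(names(f1), feature_catalogue()$name)
  expect_true(all(is.finite(f1)))
})

test_that("masked features are invariant to whole-voxel translation", {
  cases <- fixture("cohort_s3", small_case(seed = 3, n_cases = 30))
  cs <- cases[[2]]
  arr <- cs$volume$intensities
  vox <- cs$mask$voxels
  d <- dim(arr)
  shift <- function(a, fill) {
    out <- array(fill, dim = d)
    out[2:d[1], 2:d[2], 1:d[3]] <- a[1:(d[1] - 1), 1:(d[2] - 1), 1:d[3]]
    out
  }
  vol2 <- ct_volume(shift(arr, 40), cs$volume$spacing_mm)
  mask2 <- roi_mask(shift(vox, FALSE), cs$mask$spacing_mm)
  f1 <- extract_features(cs$volume, cs$mask)
  f2 <- extract_features(vol2, mask2)
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("intensity features ignore mask-preserving changes outside the ROI", {
  cases <- fixture("cohort_s3", small_case(seed = 3, n_cases = 30))
  cs <- cases[[3]]
  arr2 <- cs$volume$intensities
  arr2[!cs$mask$voxels] <- 0
  roi1 <- extract_roi(cs$volume, cs$mask)
  roi2 <- extract_roi(ct_volume(arr2, cs$volume$spacing_mm), cs$mask)
  expect_identical(roi1$values, roi2$values)
})

test_that("averaged direction aggregation is available and differs sanely", {
  lev <- random_level_array(c(5, 5, 4), 3)
  d <- as_droi(lev)
  merged <- glcm_features(d, "merged")
  avg <- glcm_features(d, "averaged")
  expect_identical(names(merged), names(avg))
  expect_true(all(is.finite(avg)))
})
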