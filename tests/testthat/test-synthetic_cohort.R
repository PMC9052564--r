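test_that("label balance is exact and stratified generation is deterministic", {
  cfg <- synthetic_cohort_config(n_cases = 20, prevalence = 0.5, seed = 7)
  cases <- generate_cohort(cfg)
  expect_length(cases, 20)
  expect_equal(sum(vapply(cases, `[[`, integer(1), "label")), 10L)
  again <- generate_cohort(cfg)
  for (i in seq_along(cases)) {
    expect_identical(cases[[i]]$volume$intensities,
                     again[[i]]$volume$intensities)
    expect_identical(cases[[i]]$mask$voxels, again[[i]]$mask$voxels)
    expect_identical(cases[[i]]$trg, again[[i]]$trg)
  }
})

test_that("TRG is consistent with the binary endpoint in every case", {
  cases <- fixture("cohort_s3", small_case(seed = 3, n_cases = 30))
  trg <- vapply(cases, `[[`, integer(1), "trg")
  lab <- vapply(cases, `[[`, integer(1), "label")
  expect_true(all(trg[lab == 1] %in% 3:4))
  expect_true(all(trg[lab == 0] %in% 0:2))
  # every mask non-empty, volumes on an HU-like scale
  expect_true(all(vapply(cases, function(cs) sum(cs$mask$voxels) > 0,
                         logical(1))))
})

test_that("equal-axis configuration yields elongation near 1", {
  cases <- generate_cohort(synthetic_cohort_config(
    n_cases = 6, elongation_range = c(1, 1), texture_effect = 0, seed = 11))
  el <- vapply(cases, function(cs)
    unname(shape_features(cs$mask)["shape_elongation"]), numeric(1))
  expect_true(all(abs(el - 1) < 0.05))
})

test_that("cohort B receives the configured site shift", {
  cfgA <- synthetic_cohort_config(n_cases = 40, site_shift_hu = 0, seed = 5)
  cfgB <- synthetic_cohort_config(n_cases = 40, site_shift_hu = 50, seed = 5)
  a <- generate_cohort(cfgA)
  b <- generate_cohort(cfgB)
  is_b <- vapply(a, `[[`, character(1), "cohort") == "B"
  for (i in which(is_b))
    expect_equal(b[[i]]$volume$intensities - a[[i]]$volume$intensities,
                 array(50, dim = dim(a[[i]]$volume$intensities)),
                 tolerance = 1e-12)
  for (i in which(!is_b))
    expect_identical(b[[i]]$volume$intensities, a[[i]]$volume$intensities)
})

test_that("configs whose ellipsoids cannot fit the grid are rejected", {
  expect_error(synthetic_cohort_config(grid_shape = c(10, 10, 4)),
               "too small")
  expect_error(synthetic_cohort_config(n_cases = 1), "n_cases")
})

test_that("written cohorts round-trip bit-exactly through the NIfTI layer", {
  dirp <- withr::local_tempdir()
  cases <- fixture("cohort_s3", small_case(seed = 3, n_cases = 30))[1:3]
  write_cohort(cases, dirp)
  back <- read_cohort(dirp)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$volume$intensities,
                 cases[[i]]$volume$intensities, tolerance = 1e-6)
    expect_identical(back[[i]]$mask$voxels, cases[[i]]$mask$voxels)
    expect_equal(back[[i]]$volume$spacing_mm, cases[[i]]$volume$spacing_mm,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$label, cases[[i]]$label)
  }
  # TRG-derived labels in the CSV follow the endpoint definition
  clin <- read_clinical_table(file.path(dirp, "clinical.csv"))
  expect_identical(unname(derive_gr_labels(clin)),
                   vapply(cases, `[[`, integer(1), "label"))
})

test_that("an empty case list still writes a valid zero-row manifest", {
  dirp <- withr::local_tempdir()
  write_cohort(list(), dirp)
  expect_length(read_cohort(dirp), 0)
  clin <- read.csv(file.path(dirp, "clinical.csv"))
  expect_equal(nrow(clin), 0)
})
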