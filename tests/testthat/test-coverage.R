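test_that("percent coverage follows the covered/total volume ratio", {
  dims <- c(20, 20, 10); sp <- c(1, 1, 2)
  tumor <- box_mask(dims, c(5, 5, 3), c(12, 12, 7), sp)    # 8x8x5 voxels
  ablation <- box_mask(dims, c(9, 5, 3), c(16, 12, 7), sp) # overlaps half in x
  res <- percent_tumor_coverage(tumor, ablation)
  expect_equal(res$percent_coverage, 50)
  expect_equal(res$tumor_volume_cm3, 8 * 8 * 5 * 2 / 1000)
  expect_equal(res$covered_volume_cm3, 4 * 8 * 5 * 2 / 1000)
  expect_lte(res$covered_volume_cm3,
             min(res$tumor_volume_cm3, res$ablation_volume_cm3))

  inside <- percent_tumor_coverage(
    box_mask(dims, c(6, 6, 4), c(10, 10, 6), sp),
    box_mask(dims, c(5, 5, 3), c(12, 12, 7), sp))
  expect_equal(inside$percent_coverage, 100)

  apart <- percent_tumor_coverage(
    box_mask(dims, c(1, 1, 1), c(4, 4, 2), sp),
    box_mask(dims, c(10, 10, 5), c(14, 14, 8), sp))
  expect_equal(apart$percent_coverage, 0)
})

test_that("coverage ratio is asymmetric but covered volume is not", {
  dims <- c(16, 16, 8)
  small <- box_mask(dims, c(4, 4, 2), c(7, 7, 5))   # 4x4x4
  large <- box_mask(dims, c(6, 4, 2), c(13, 7, 5))  # 8x4x4, overlap 2x4x4
  ab <- percent_tumor_coverage(small, large)
  ba <- percent_tumor_coverage(large, small)
  expect_equal(ab$covered_volume_cm3, ba$covered_volume_cm3)
  expect_false(isTRUE(all.equal(ab$percent_coverage, ba$percent_coverage)))
  expect_equal(ab$percent_coverage, 100 * 2 / 4)
  expect_equal(ba$percent_coverage, 100 * 2 / 8)
})

test_that("coverage is invariant under joint in-plane 90-degree rotation", {
  spec <- phantom_spec(grid_shape = c(48, 48, 16), spacing = c(2, 2, 4),
                       tumor_center = c(40, 52, 30), tumor_radii = c(14, 10, 12),
                       ablation_center = c(50, 46, 36), ablation_radii = c(15, 13, 14),
                       seed = 2)
  case <- generate_case(spec)
  rot <- function(lv) {
    m <- lv$mask
    rotated <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE]
    label_volume(rotated, lv$spacing)
  }
  base <- percent_tumor_coverage(case$tumor_mask, case$ablation_mask)
  turned <- percent_tumor_coverage(rot(case$tumor_mask), rot(case$ablation_mask))
  expect_equal(turned$percent_coverage, base$percent_coverage)
})

test_that("degenerate coverage inputs raise classed errors", {
  dims <- c(8, 8, 4)
  empty <- label_volume(array(FALSE, dims), c(1, 1, 1))
  full <- box_mask(dims, c(1, 1, 1), c(8, 8, 4))
  expect_error(percent_tumor_coverage(empty, full),
               class = "slicecov_empty_mask")
  other_grid <- box_mask(c(8, 8, 5), c(1, 1, 1), c(4, 4, 2))
  expect_error(percent_tumor_coverage(full, other_grid),
               class = "slicecov_grid_mismatch")
  other_spacing <- label_volume(full$mask, c(1, 1, 2))
  expect_error(percent_tumor_coverage(full, other_spacing),
               class = "slicecov_grid_mismatch")
  expect_error(label_volume(array(TRUE, dims), c(1, 0, 1)),
               class = "slicecov_bad_spacing")
})

test_that("equivalent sphere diameters match the clinical size convention", {
  expect_equal(round(equivalent_sphere_diameter(31.8), 1), 3.9)
  expect_equal(round(equivalent_sphere_diameter(49.3), 1), 4.5)
  # inverse identity: a unit-diameter sphere has volume pi/6
  expect_equal(equivalent_sphere_diameter(pi / 6), 1.0, tolerance = 1e-12)
  expect_error(equivalent_sphere_diameter(0), class = "slicecov_domain_error")
  expect_error(equivalent_sphere_diameter(-3), class = "slicecov_domain_error")
})

test_that("registration quality is exact on self- and offset-comparisons", {
  img <- withr::with_seed(1, matrix(runif(64 * 64), 64, 64))
  self <- registration_quality(img, img)
  expect_equal(self$ssim, 1)
  expect_equal(self$standard_error, 0)

  offset <- registration_quality(img, img + 0.5)
  expect_equal(offset$standard_error, 0) # constant shift has zero variance
  expect_lt(offset$ssim, 1)              # but is penalized by SSIM luminance

  expect_error(registration_quality(img, img[1:32, 1:32]),
               class = "slicecov_grid_mismatch")
})

test_that("independent noise fields have SSIM near zero", {
  ssims <- vapply(1:5, function(s) {
    a <- withr::with_seed(s, matrix(rnorm(128^2), 128, 128))
    b <- withr::with_seed(s + 100, matrix(rnorm(128^2), 128, 128))
    registration_quality(a, b)$ssim
  }, numeric(1))
  expect_true(all(abs(ssims) < 0.1))
})

test_that("registration quality accepts 3D volumes", {
  vol <- withr::with_seed(2, array(rnorm(32 * 32 * 4), c(32, 32, 4)))
  self <- registration_quality(vol, vol)
  expect_equal(self$ssim, 1)
  expect_equal(self$standard_error, 0)
})
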