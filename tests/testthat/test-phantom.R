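test_that("contained and disjoint ellipsoids give 100% and 0% coverage", {
  contained <- generate_case(small_phantom_spec())
  expect_equal(contained$true_coverage, 100)

  disjoint <- generate_case(phantom_spec(
    grid_shape = c(64, 64, 20), spacing = c(2, 2, 4),
    tumor_center = c(35, 64, 40), tumor_radii = rep(12, 3),
    ablation_center = c(95, 64, 40), ablation_radii = rep(14, 3)))
  expect_equal(disjoint$true_coverage, 0)
})

test_that("identical spec reproduces bit-identical volumes and masks", {
  a <- generate_case(small_phantom_spec(seed = 11))
  b <- generate_case(small_phantom_spec(seed = 11))
  expect_identical(a$pre_volume, b$pre_volume)
  expect_identical(a$post_volume, b$post_volume)
  expect_identical(a$tumor_mask$mask, b$tumor_mask$mask)
  expect_identical(a$true_coverage, b$true_coverage)

  c <- generate_case(small_phantom_spec(seed = 12))
  expect_false(identical(a$pre_volume, c$pre_volume))
})

test_that("a case's stored coverage is self-consistent with its own masks", {
  case <- generate_case(phantom_spec(
    grid_shape = c(64, 64, 20), spacing = c(2, 2, 4),
    tumor_radii = rep(15, 3), ablation_radii = rep(17, 3),
    ablation_center = c(64, 64, 40) + c(0, 0, 12), seed = 3))
  recount <- percent_tumor_coverage(case$tumor_mask, case$ablation_mask)
  expect_identical(case$true_coverage, recount$percent_coverage)
  expect_gt(case$true_coverage, 0)
  expect_lt(case$true_coverage, 100)
})

test_that("ellipsoids exceeding the grid are a configuration error", {
  expect_error(
    phantom_spec(grid_shape = c(32, 32, 10), spacing = c(2, 2, 4),
                 tumor_radii = rep(40, 3)),
    class = "slicecov_config_error")
  expect_error(phantom_spec(tumor_radii = c(10, -5, 10)),
               class = "slicecov_config_error")
})

test_that("shared landmarks shift axially between pre and post volumes", {
  spec <- small_phantom_spec(axial_offset = 8, seed = 5) # 2 slices at 4 mm
  case <- generate_case(spec)
  bg <- slicecov:::generate_background(spec)
  # away from both lesions, post slice k matches the background at k - 2
  k <- 18
  corr_shifted <- cor(as.numeric(case$post_volume[1:15, 1:15, k]),
                      as.numeric(bg[1:15, 1:15, k - 2]))
  corr_unshifted <- cor(as.numeric(case$post_volume[1:15, 1:15, k]),
                        as.numeric(bg[1:15, 1:15, k]))
  expect_gt(corr_shifted, corr_unshifted)
  expect_gt(corr_shifted, 0.7)
})

test_that("cohort generation hits coverage targets within 2 points, deterministically", {
  targets <- withr::with_seed(7, runif(182, 20, 100))
  cohort <- generate_cohort(182, targets, seed = 7)
  expect_equal(nrow(cohort), 182)
  expect_true(all(cohort$status == "ok"))
  expect_lte(max(abs(cohort$true_coverage - cohort$target_coverage)), 2)

  again <- generate_cohort(182, targets, seed = 7)
  expect_identical(cohort$true_coverage, again$true_coverage)

  # a regenerated case reproduces the manifest's voxel-counted coverage
  i <- which.min(cohort$true_coverage)
  case <- generate_case(cohort$spec[[i]], case_id = cohort$case_id[i])
  expect_equal(case$true_coverage, cohort$true_coverage[i], tolerance = 1e-12)
})

test_that("all-100% targets are realized exactly and low-coverage cases shift axially", {
  cohort <- generate_cohort(10, rep(100, 10), seed = 3)
  expect_true(all(cohort$true_coverage == 100))
  expect_true(all(cohort$axial_shift_mm == 0))

  low <- generate_cohort(4, rep(25, 4), seed = 3)
  expect_true(all(abs(low$axial_shift_mm) > 10))
})

test_that("unreachable targets are reported per case, not silently dropped", {
  expect_warning(
    cohort <- generate_cohort(3, c(100, 100, 40), seed = 1, shrink = 0.5),
    "unreachable")
  expect_equal(cohort$status[1:2], c("unreachable", "unreachable"))
  expect_equal(cohort$status[3], "ok")
  expect_true(all(is.na(cohort$true_coverage[1:2])))
})

test_that("cohort argument contracts are enforced", {
  expect_error(generate_cohort(3, c(50, 60), seed = 1),
               class = "slicecov_config_error")
  expect_error(generate_cohort(2, c(50, 140), seed = 1),
               class = "slicecov_config_error")
})

test_that("voxel-counted sphere overlap converges to the closed form as spacing shrinks", {
  errs <- lapply(c(2, 1, 0.5), sphere_coverage_errors)
  expect_true(all(errs[[2]] < 0.02)) # within 2% at 1 mm, any grid phase
  expect_true(all(diff(vapply(errs, mean, numeric(1))) <= 0))
})

test_that("coverage is invariant to translating both masks together", {
  gs <- c(40, 40, 20); sp <- c(2, 2, 2)
  mk <- function(shift) {
    t <- label_volume(slicecov:::ellipsoid_mask_array(
      gs, sp, c(30, 30, 16) + shift, c(12, 10, 8)), sp)
    a <- label_volume(slicecov:::ellipsoid_mask_array(
      gs, sp, c(36, 30, 16) + shift, c(14, 12, 10)), sp)
    percent_tumor_coverage(t, a)$percent_coverage
  }
  base <- mk(c(0, 0, 0))
  expect_gt(base, 0)
  # whole-voxel translations preserve the sampled geometry exactly
  expect_equal(mk(c(6, -4, 2)), base, tolerance = 1e-12)
})

test_that("cohorts round-trip through NIfTI with spacing and coverage intact", {
  dir <- withr::local_tempdir()
  # small grid, so draw proportionally small tumors
  cohort <- generate_cohort(2, c(80, 45), seed = 2,
                            grid_shape = c(48, 48, 16), spacing = c(2, 2, 4),
                            tumor_volume_mean_cm3 = 8, tumor_volume_sd_cm3 = 3)
  manifest <- write_cohort_nifti(cohort, dir)
  expect_true(all(file.exists(manifest$tumor_path)))
  tumor <- read_label_volume(manifest$tumor_path[1])
  ablation <- read_label_volume(manifest$ablation_path[1])
  expect_equal(tumor$spacing, c(2, 2, 4))
  expect_equal(percent_tumor_coverage(tumor, ablation)$percent_coverage,
               manifest$true_coverage[1], tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
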