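# Fixtures are built in code; nothing is read from disk.

# Independent AUC oracle: fraction of (positive, negative) pairs ranked
# correctly, ties counted 1/2. Quadratic brute force, for small n only.
auc_pair_count <- function(positive, scores) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (p in sp) total <- total + sum(p > sn) + 0.5 * sum(p == sn)
  total / (length(sp) * length(sn))
}

# Axis-aligned box mask as a label_volume.
box_mask <- function(dims, from, to, spacing = c(1, 1, 1)) {
  m <- array(FALSE, dims)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  label_volume(m, spacing)
}

# Sphere pair used by the analytic-overlap checks: radii 20 and 25 mm,
# centers 10 mm apart along x, on an isotropic grid of the given spacing.
# `phase` shifts both centers together by a fraction of a voxel: voxel
# counting error oscillates with the grid phase, so convergence is judged
# on the phase-averaged error.
overlap_sphere_masks <- function(spacing_mm, phase = 0) {
  gs <- rep(ceiling(104 / spacing_mm), 3)
  sp <- rep(spacing_mm, 3)
  ctr <- c(36, 52, 52) + phase * spacing_mm
  tumor <- label_volume(
    slicecov:::ellipsoid_mask_array(gs, sp, ctr, rep(20, 3)), sp)
  ablation <- label_volume(
    slicecov:::ellipsoid_mask_array(gs, sp, ctr + c(10, 0, 0), rep(25, 3)), sp)
  list(tumor = tumor, ablation = ablation,
       exact_coverage = 100 * sphere_intersection_volume(20, 25, 10) /
         (4 / 3 * pi * 20^3))
}

# Relative voxel-counting errors of the sphere-pair coverage at one spacing,
# over a fixed set of sub-voxel grid phases.
sphere_coverage_errors <- function(spacing_mm, phases = c(0, 0.25, 0.5, 0.75)) {
  vapply(phases, function(ph) {
    f <- overlap_sphere_masks(spacing_mm, phase = ph)
    got <- percent_tumor_coverage(f$tumor, f$ablation)$percent_coverage
    abs(got - f$exact_coverage) / f$exact_coverage
  }, numeric(1))
}

# Small slice image with reproducible pixels.
tiny_slice <- function(case_id, roi_kind = "tumor", n = 16, seed = 1) {
  px <- withr::with_seed(seed, matrix(stats::runif(n * n), n, n))
  slice_image(px, case_id = case_id, roi_kind = roi_kind, slice_index = 1L,
              window = c(0, 1))
}

# Case-pair table shaped like make_case_pairs() output but with tiny slices,
# for combinatorics tests where pixel content is irrelevant.
tiny_pairs <- function(n, seed = 1, size = 16) {
  ids <- sprintf("case_%03d", seq_len(n))
  cov <- withr::with_seed(seed, stats::runif(n, 0, 100))
  tibble::tibble(
    case_id = ids,
    coverage = cov,
    tumor_slice = purrr::map(seq_len(n), function(i) {
      tiny_slice(ids[i], "tumor", n = size, seed = seed + i)
    }),
    ablation_slice = purrr::map(seq_len(n), function(i) {
      tiny_slice(ids[i], "ablation", n = size, seed = seed + 10000 + i)
    })
  )
}

# Small, quick phantom spec (coarse grid, fine enough for geometry checks).
small_phantom_spec <- function(..., seed = 1) {
  phantom_spec(grid_shape = c(64, 64, 20), spacing = c(2, 2, 4),
               tumor_radii = rep(15, 3), ablation_radii = rep(18, 3),
               seed = seed, ...)
}
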