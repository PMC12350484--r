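#' Specify a synthetic ablation phantom
#'
#' Describes one paired pseudo-CT case: an ellipsoidal arterially-enhancing
#' tumor on the pre-ablation volume and an ellipsoidal devascularized
#' ablation zone on the post-ablation volume, sharing a structured
#' background (liver-like texture, rib-like arcs whose radius drifts with
#' the axial position, and a diaphragm-like soft edge). The background gives
#' the feature extractor out-of-plane landmarks, so slices taken at
#' different axial positions genuinely look different — the mechanism a
#' slice-based coverage estimator relies on.
#'
#' Intensities are pseudo-HU with a plausible contrast ordering (liver 60,
#' enhancing tumor 110, devascularized ablation 20); only the ordering and
#' rough magnitudes matter because images are windowed downstream.
#'
#' @param grid_shape Integer length 3, voxels per axis (axial = 3rd axis).
#' @param spacing mm per voxel per axis; the 5 mm default axial spacing
#'   matches routine multi-slice abdominal CT reconstructions.
#' @param tumor_center,ablation_center mm coordinates; default grid center.
#' @param tumor_radii,ablation_radii mm semi-axes. Defaults are spheres
#'   matching mean clinical tumor (31.8 cm^3) and ablation (49.3 cm^3)
#'   volumes.
#' @param axial_offset mm displacement of the shared background between the
#'   pre and post volumes (misregistration surrogate); masks are unaffected.
#' @param shrink Factor in (0, 1] applied to the ablation cranio-caudal
#'   semi-axis, emulating late ablation-zone shrinkage along one diameter.
#'   Default 1 (off).
#' @param background List of background-texture parameters; see Details
#'   source for fields (noise sd, smoothing sigma, rib count/geometry,
#'   diaphragm edge).
#' @param intensity List with `liver`, `tumor`, `ablation` mean pseudo-HU
#'   and `noise_sd` for the per-volume i.i.d. noise.
#' @param seed Integer; the case is bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(seed = 1)
#' case <- generate_case(spec)
#' case$true_coverage
phantom_spec <- function(grid_shape = c(320, 320, 40),
                         spacing = c(1, 1, 5),
                         tumor_center = NULL,
                         tumor_radii = rep(19.65, 3),
                         ablation_center = NULL,
                         ablation_radii = rep(22.74, 3),
                         axial_offset = 0,
                         shrink = 1,
                         background = list(),
                         intensity = list(),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  extent <- grid_shape * spacing
  if (is.null(tumor_center)) tumor_center <- extent / 2
  if (is.null(ablation_center)) ablation_center <- tumor_center
  bg <- utils::modifyList(list(
    noise_sd = 15, smooth_sigma_mm = c(6, 6, 7.5),
    n_ribs = 3, rib_intensity = 240, rib_thickness_mm = 3.5,
    rib_radius_mm = 0.44 * min(extent[1:2]), rib_radius_slope = 0.3,
    rib_arc_deg = 40,
    diaphragm_intensity = -45, diaphragm_softness_mm = 3,
    diaphragm_slope = 0.6
  ), background)
  inten <- utils::modifyList(
    list(liver = 60, tumor = 110, ablation = 20, noise_sd = 10), intensity)
  spec <- structure(
    list(grid_shape = grid_shape, spacing = spacing,
         tumor_center = as.numeric(tumor_center),
         tumor_radii = as.numeric(tumor_radii),
         ablation_center = as.numeric(ablation_center),
         ablation_radii = as.numeric(ablation_radii),
         axial_offset = axial_offset, shrink = shrink,
         background = bg, intensity = inten, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$tumor_radii <= 0) || any(spec$ablation_radii <= 0)) {
    stop_slicecov("Ellipsoid radii must be strictly positive.",
                  "slicecov_config_error")
  }
  if (spec$shrink <= 0 || spec$shrink > 1) {
    stop_slicecov("`shrink` must be in (0, 1].", "slicecov_config_error")
  }
  ok_t <- ellipsoid_fits(spec$grid_shape, spec$spacing,
                         spec$tumor_center, spec$tumor_radii)
  ok_a <- ellipsoid_fits(spec$grid_shape, spec$spacing,
                         spec$ablation_center, effective_ablation_radii(spec))
  if (!ok_t || !ok_a) {
    stop_slicecov("Ellipsoid does not fit inside the phantom grid.",
                  "slicecov_config_error")
  }
  invisible(spec)
}

effective_ablation_radii <- function(spec) {
  spec$ablation_radii * c(1, 1, spec$shrink)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$grid_shape, collapse = "x"),
      " @ ", paste(x$spacing, collapse = "x"), " mm, tumor r = (",
      paste(signif(x$tumor_radii, 3), collapse = ", "), ") mm, ablation r = (",
      paste(signif(x$ablation_radii, 3), collapse = ", "),
      ") mm, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Separable Gaussian smoothing of a 3D array (sigma per axis, voxels).
smooth3d <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    G <- gaussian_band_matrix(d[ax], sigma_vox[ax],
                              half = max(2L, ceiling(3 * sigma_vox[ax])))
    perm <- c(ax, setdiff(1:3, ax))
    y <- aperm(x, perm)
    dim(y) <- c(d[ax], prod(d[-ax]))
    y <- G %*% y
    dim(y) <- d[perm]
    x <- aperm(y, order(perm))
  }
  x
}

# Shared structured background: liver base + smoothed noise + rib arcs whose
# ring radius drifts linearly with z + a tilted soft diaphragm-like edge.
generate_background <- function(spec) {
  gs <- spec$grid_shape; sp <- spec$spacing
  bg <- spec$background
  ax <- grid_axes_mm(gs, sp)
  # Texture is generated on an in-plane grid coarsened by `cf` and
  # bilinearly upsampled: the smoothing correlation length (>= 4 mm) is
  # far above the fine-grid Nyquist, so this only buys speed.
  cf <- if (all(gs[1:2] %% 4 == 0) && all(gs[1:2] >= 128)) 4L else 1L
  cgs <- c(gs[1] %/% cf, gs[2] %/% cf, gs[3])
  csp <- c(sp[1] * cf, sp[2] * cf, sp[3])
  vol <- withr::with_seed(sub_seed(spec$seed, "background"), {
    noise <- array(stats::rnorm(prod(cgs)), cgs)
    noise <- smooth3d(noise, bg$smooth_sigma_mm / csp)
    noise / stats::sd(noise) * bg$noise_sd
  })
  if (cf > 1L) {
    fine <- array(0, gs)
    for (k in seq_len(gs[3])) {
      fine[, , k] <- EBImage::resize(vol[, , k], w = gs[1], h = gs[2])
    }
    vol <- fine
  }
  vol <- spec$intensity$liver + vol
  cx <- mean(range(ax[[1]])); cy <- mean(range(ax[[2]]))
  r_in <- sqrt(outer((ax[[1]] - cx)^2, (ax[[2]] - cy)^2, `+`))
  theta <- atan2(outer(rep(1, gs[1]), ax[[2]] - cy),
                 outer(ax[[1]] - cx, rep(1, gs[2])))
  arc_centers <- seq(-pi / 2, pi / 2, length.out = bg$n_ribs + 2)[-c(1, bg$n_ribs + 2)]
  half_arc <- bg$rib_arc_deg / 2 * pi / 180
  in_arc <- Reduce(`|`, lapply(arc_centers, function(a0) {
    da <- abs(atan2(sin(theta - a0), cos(theta - a0)))
    da <= half_arc
  }))
  z_mid <- mean(range(ax[[3]]))
  y_edge0 <- cy + 0.25 * (max(ax[[2]]) - cy)
  Ymat <- outer(rep(1, gs[1]), ax[[2]])
  for (k in seq_len(gs[3])) {
    z <- ax[[3]][k]
    Rz <- bg$rib_radius_mm - bg$rib_radius_slope * (z - z_mid)
    rib <- in_arc & abs(r_in - Rz) <= bg$rib_thickness_mm / 2
    slice <- vol[, , k]
    slice[rib] <- slice[rib] + bg$rib_intensity
    edge <- 1 / (1 + exp(-(Ymat - (y_edge0 + bg$diaphragm_slope * (z - z_mid))) /
                           bg$diaphragm_softness_mm))
    vol[, , k] <- slice + bg$diaphragm_intensity * edge
  }
  vol
}

# Shift an array along the axial axis by an integer number of slices,
# replicating edge slices (misregistration surrogate).
shift_axial <- function(x, n_slices) {
  if (n_slices == 0) return(x)
  k <- dim(x)[3]
  idx <- clip(seq_len(k) - n_slices, 1, k)
  x[, , idx, drop = FALSE]
}

#' Generate one synthetic paired case
#'
#' Renders the pre- and post-ablation pseudo-CT volumes and masks described
#' by a [phantom_spec()], and computes the case's true volumetric coverage
#' by voxel counting of its own masks (self-consistent ground truth).
#'
#' @param spec A [phantom_spec()].
#' @param case_id Identifier attached to the case (default `"phantom"`).
#' @return An object of class `phantom_case`: list with `pre_volume`,
#'   `post_volume` (3D pseudo-HU arrays), `tumor_mask`, `ablation_mask`
#'   ([label_volume()]s), `true_coverage` (percent), `coverage` (the full
#'   [percent_tumor_coverage()] row), `case_id` and `spec`.
#' @export
generate_case <- function(spec, case_id = "phantom") {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape; sp <- spec$spacing
  bg <- generate_background(spec)
  tumor <- label_volume(
    ellipsoid_mask_array(gs, sp, spec$tumor_center, spec$tumor_radii), sp)
  ablation <- label_volume(
    ellipsoid_mask_array(gs, sp, spec$ablation_center,
                         effective_ablation_radii(spec)), sp)
  pre <- bg
  pre[tumor$mask] <- spec$intensity$tumor
  pre <- pre + withr::with_seed(
    sub_seed(spec$seed, "noise", "pre"),
    array(stats::rnorm(prod(gs), sd = spec$intensity$noise_sd), gs))
  post <- shift_axial(bg, as.integer(round_half_up(spec$axial_offset / sp[3])))
  post[ablation$mask] <- spec$intensity$ablation
  post <- post + withr::with_seed(
    sub_seed(spec$seed, "noise", "post"),
    array(stats::rnorm(prod(gs), sd = spec$intensity$noise_sd), gs))
  cov <- percent_tumor_coverage(tumor, ablation)
  structure(
    list(pre_volume = pre, post_volume = post,
         tumor_mask = tumor, ablation_mask = ablation,
         true_coverage = cov$percent_coverage, coverage = cov,
         case_id = case_id, spec = spec),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", x$case_id, ": ",
      paste(dim(x$pre_volume), collapse = "x"), " voxels, true coverage ",
      sprintf("%.1f%%", x$true_coverage), "\n", sep = "")
  invisible(x)
}

# Percent of the tumor ellipsoid covered by the ablation ellipsoid, counted
# on the tumor's bounding sub-grid only (cheap inner loop for the solver).
ellipsoid_coverage_percent <- function(gs, sp, t_center, t_radii,
                                       a_center, a_radii) {
  ax <- grid_axes_mm(gs, sp)
  sub <- lapply(1:3, function(a) {
    which(ax[[a]] >= t_center[a] - t_radii[a] - sp[a] &
            ax[[a]] <= t_center[a] + t_radii[a] + sp[a])
  })
  qsum <- function(center, radii) {
    u1 <- ((ax[[1]][sub[[1]]] - center[1]) / radii[1])^2
    u2 <- ((ax[[2]][sub[[2]]] - center[2]) / radii[2])^2
    u3 <- ((ax[[3]][sub[[3]]] - center[3]) / radii[3])^2
    outer(outer(u1, u2, `+`), u3, `+`) <= 1
  }
  tm <- qsum(t_center, t_radii)
  am <- qsum(a_center, a_radii)
  100 * sum(tm & am) / sum(tm)
}

#' Generate a cohort of phantoms hitting prescribed coverage targets
#'
#' For each requested coverage value, draws a tumor (lognormal volume,
#' mildly anisotropic ellipsoid) and a concentric, proportionally larger
#' ablation zone, then solves the axial (cranio-caudal) displacement of the
#' ablation center by 1D bisection so that the voxel-counted coverage hits
#' the target. Driving coverage through the axial offset means low-coverage
#' cases have tumor and ablation isocenters on genuinely different axial
#' planes — the imaging signature the slice-based estimator learns from.
#'
#' Targets that cannot be realized with the drawn geometry (e.g. 100%
#' requested while `shrink < 1` prevents containment) are reported with
#' `status = "unreachable"` rather than silently dropped.
#'
#' @param n Number of cases; must equal `length(coverage_targets)`.
#' @param coverage_targets Numeric vector of desired percent coverages in
#'   `[0, 100]`.
#' @param seed Integer; the whole cohort is deterministic given `seed`, and
#'   each case's spec embeds its own derived sub-seed.
#' @param grid_shape,spacing Phantom grid (see [phantom_spec()]).
#' @param tumor_volume_mean_cm3,tumor_volume_sd_cm3 Lognormal tumor-volume
#'   population; defaults match a mean 31.8 and sd 27.6 cm^3 clinical
#'   regime (volumes clamped to fit the grid).
#' @param ablation_volume_ratio Mean ablation/tumor volume ratio (default
#'   49.3/31.8).
#' @param shrink Ablation cranio-caudal shrink factor, passed through to
#'   each [phantom_spec()].
#' @param center_jitter_mm Uniform jitter of the tumor center around the
#'   grid center, per axis.
#' @param tol_pp Bisection stopping tolerance on coverage, percentage points.
#' @return A tibble with one row per case: `case_id`, `target_coverage`,
#'   `true_coverage` (realized, voxel-counted), `status` (`"ok"` or
#'   `"unreachable"`), `tumor_volume_cm3`, `ablation_volume_cm3`,
#'   `axial_shift_mm`, and a `spec` list-column of [phantom_spec()]s from
#'   which [generate_case()] reproduces the full volumes on demand.
#' @export
#' @examples
#' cohort <- generate_cohort(3, c(100, 60, 25), seed = 7)
#' cohort[, c("case_id", "target_coverage", "true_coverage", "status")]
generate_cohort <- function(n, coverage_targets, seed,
                            grid_shape = c(320, 320, 40),
                            spacing = c(1, 1, 5),
                            tumor_volume_mean_cm3 = 31.8,
                            tumor_volume_sd_cm3 = 27.6,
                            ablation_volume_ratio = 49.3 / 31.8,
                            shrink = 1,
                            center_jitter_mm = 5,
                            tol_pp = 0.25) {
  coverage_targets <- as.numeric(coverage_targets)
  if (length(coverage_targets) != n) {
    stop_slicecov("`n` must equal `length(coverage_targets)`.",
                  "slicecov_config_error")
  }
  if (any(coverage_targets < 0 | coverage_targets > 100)) {
    stop_slicecov("Coverage targets must lie in [0, 100].",
                  "slicecov_config_error")
  }
  extent <- grid_shape * spacing
  cv <- tumor_volume_sd_cm3 / tumor_volume_mean_cm3
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(tumor_volume_mean_cm3) - sdlog^2 / 2
  rows <- purrr::map(seq_len(n), function(i) {
    case_id <- sprintf("case_%03d", i)
    target <- coverage_targets[i]
    draws <- withr::with_seed(sub_seed(seed, "cohort-geometry", case_id), {
      v <- clip(stats::rlnorm(1, meanlog, sdlog), 6, 60)
      f <- exp(stats::runif(3, -0.12, 0.12))
      f <- f / prod(f)^(1 / 3)
      scale_a <- ablation_volume_ratio^(1 / 3) * exp(stats::runif(3, -0.04, 0.04))
      jit <- stats::runif(3, -center_jitter_mm, center_jitter_mm)
      list(v = v, f = f, scale_a = scale_a, jit = jit)
    })
    r0 <- (3 * draws$v * 1000 / (4 * pi))^(1 / 3)
    t_radii <- r0 * draws$f
    a_radii <- t_radii * draws$scale_a
    a_eff <- a_radii * c(1, 1, shrink)
    t_center <- extent / 2 + draws$jit
    cov_at <- function(dz) {
      ellipsoid_coverage_percent(grid_shape, spacing, t_center, t_radii,
                                 t_center + c(0, 0, dz), a_eff)
    }
    # Largest |dz| in each axial direction for which the ablation still
    # fits the grid; the search never probes outside it.
    dz_fit_max <- function(dir) {
      full <- t_radii[3] + a_eff[3] + spacing[3] # beyond this, overlap is 0
      lim <- if (dir > 0) {
        extent[3] - (t_center[3] + a_eff[3])
      } else {
        t_center[3] - a_eff[3]
      }
      max(0, min(full, lim))
    }
    cov0 <- cov_at(0)
    status <- "ok"
    dz <- 0
    if (cov0 < target - 2) {
      status <- "unreachable"
    } else if (target < cov0) {
      solved <- FALSE
      for (dir in c(1, -1)) {
        dzm <- dz_fit_max(dir)
        if (dzm <= 0 || cov_at(dir * dzm) > target + 2) next
        lo <- 0; hi <- dzm
        for (iter in 1:60) {
          mid <- (lo + hi) / 2
          cm <- cov_at(dir * mid)
          dz <- dir * mid
          if (abs(cm - target) <= tol_pp) break
          if (cm > target) lo <- mid else hi <- mid
        }
        solved <- TRUE
        break
      }
      if (!solved) status <- "unreachable"
    }
    if (status == "ok") {
      spec <- phantom_spec(
        grid_shape = grid_shape, spacing = spacing,
        tumor_center = t_center, tumor_radii = t_radii,
        ablation_center = t_center + c(0, 0, dz), ablation_radii = a_radii,
        shrink = shrink,
        seed = sub_seed(seed, "phantom-case", case_id))
      realized <- ellipsoid_coverage_percent(
        grid_shape, spacing, t_center, t_radii,
        spec$ablation_center, effective_ablation_radii(spec))
      tibble::tibble(
        case_id = case_id, target_coverage = target, true_coverage = realized,
        status = "ok",
        tumor_volume_cm3 = 4 / 3 * pi * prod(t_radii) / 1000,
        ablation_volume_cm3 = 4 / 3 * pi * prod(a_eff) / 1000,
        axial_shift_mm = dz, spec = list(spec))
    } else {
      tibble::tibble(
        case_id = case_id, target_coverage = target, true_coverage = NA_real_,
        status = "unreachable",
        tumor_volume_cm3 = 4 / 3 * pi * prod(t_radii) / 1000,
        ablation_volume_cm3 = 4 / 3 * pi * prod(a_eff) / 1000,
        axial_shift_mm = NA_real_, spec = list(NULL))
    }
  })
  out <- dplyr::bind_rows(rows)
  n_bad <- sum(out$status != "ok")
  if (n_bad > 0) {
    warn(sprintf("%d of %d coverage targets were unreachable for the drawn geometry.",
                 n_bad, n))
  }
  out
}

#' Write a phantom cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' Renders each case of a [generate_cohort()] tibble and writes
#' `pre`/`post` volumes and `tumor`/`ablation` masks as `.nii.gz` with the
#' grid spacing in the header, alongside `manifest.csv` (case_id, paths,
#' true coverage).
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- cohort[cohort$status == "ok", ]
  manifest <- purrr::map(seq_len(nrow(ok)), function(i) {
    case <- generate_case(ok$spec[[i]], case_id = ok$case_id[i])
    paths <- file.path(dir, paste0(case$case_id, "_",
                                   c("pre", "post", "tumor", "ablation"),
                                   ".nii.gz"))
    write_nifti_volume(case$pre_volume, paths[1], spacing = case$spec$spacing)
    write_nifti_volume(case$post_volume, paths[2], spacing = case$spec$spacing)
    write_nifti_volume(case$tumor_mask, paths[3])
    write_nifti_volume(case$ablation_mask, paths[4])
    tibble::tibble(case_id = case$case_id,
                   pre_path = paths[1], post_path = paths[2],
                   tumor_path = paths[3], ablation_path = paths[4],
                   true_coverage = case$true_coverage)
  })
  manifest <- dplyr::bind_rows(manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
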