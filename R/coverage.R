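#' Volumetric percent tumor coverage from paired masks
#'
#' The ground-truth treatment endpoint: the fraction of the tumor volume
#' that lies inside the ablation zone, computed by voxel counting on two
#' registered binary masks sharing one grid,
#' \deqn{\mathrm{coverage} = 100 \times V(\mathrm{tumor} \cap \mathrm{ablation}) / V(\mathrm{tumor}).}
#' Equivalent sphere diameters of both regions are reported alongside so
#' results can be compared with clinically quoted lesion sizes.
#'
#' @param tumor,ablation [label_volume()] masks on the same grid (shape and
#'   spacing). The tumor mask must be nonempty; resample beforehand if the
#'   native grids differ.
#' @return A one-row tibble with columns `tumor_volume_cm3`,
#'   `ablation_volume_cm3`, `covered_volume_cm3`, `percent_coverage`,
#'   `tumor_equiv_diameter_cm`, `ablation_equiv_diameter_cm`.
#' @export
#' @examples
#' m <- array(FALSE, c(20, 20, 10)); a <- m
#' m[5:12, 5:12, 3:7] <- TRUE
#' a[7:16, 7:16, 3:8] <- TRUE
#' percent_tumor_coverage(label_volume(m, c(1, 1, 2)), label_volume(a, c(1, 1, 2)))
percent_tumor_coverage <- function(tumor, ablation) {
  stopifnot(is_label_volume(tumor), is_label_volume(ablation))
  check_same_grid(tumor, ablation)
  n_tumor <- sum(tumor$mask)
  if (n_tumor == 0) {
    stop_slicecov("Tumor mask is empty; percent coverage is undefined.",
                  "slicecov_empty_mask")
  }
  vox_cm3 <- prod(tumor$spacing) / 1000
  n_abl <- sum(ablation$mask)
  n_cov <- sum(tumor$mask & ablation$mask)
  tv <- n_tumor * vox_cm3
  av <- n_abl * vox_cm3
  tibble::tibble(
    tumor_volume_cm3 = tv,
    ablation_volume_cm3 = av,
    covered_volume_cm3 = n_cov * vox_cm3,
    percent_coverage = 100 * n_cov / n_tumor,
    tumor_equiv_diameter_cm = equivalent_sphere_diameter(tv),
    ablation_equiv_diameter_cm = if (av > 0) equivalent_sphere_diameter(av) else NA_real_
  )
}

#' Equivalent sphere diameter of a volume
#'
#' Diameter of the sphere with the same volume as an irregular region,
#' `d = (6 V / pi)^(1/3)`; the conventional way to express a segmented
#' lesion volume as a single size.
#'
#' @param volume_cm3 Volume in cm^3, > 0 (vectorized).
#' @return Diameter in cm.
#' @export
#' @examples
#' equivalent_sphere_diameter(31.8) # ~3.9 cm
equivalent_sphere_diameter <- function(volume_cm3) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0)) {
    stop_slicecov("`volume_cm3` must be finite and > 0.", "slicecov_domain_error")
  }
  (6 * volume_cm3 / pi)^(1 / 3)
}

#' Registration quality between two intensity images
#'
#' Agreement metrics for a registered image pair: the structural similarity
#' index (SSIM; mean over local 11x11 Gaussian-weighted windows, the
#' standard constants `K1 = 0.01`, `K2 = 0.03`) and the standard error of
#' the voxelwise intensity differences, `sd(a - b) / sqrt(N)`. For 3D input
#' the SSIM is the mean over axial slices. Note that a constant intensity
#' offset gives a standard error of exactly zero (the differences have no
#' variance) while SSIM is penalized through its luminance term.
#'
#' @param image_a,image_b Numeric 2D matrices or 3D arrays of identical shape.
#' @param dynamic_range Intensity range `L` used by the SSIM constants;
#'   defaults to the observed range across both images (minimum 1e-8).
#' @return A one-row tibble with columns `ssim` and `standard_error`.
#' @export
registration_quality <- function(image_a, image_b, dynamic_range = NULL) {
  da <- dim(image_a) %||% length(image_a)
  db <- dim(image_b) %||% length(image_b)
  if (!identical(da, db)) {
    stop_slicecov("Images must have identical shapes.", "slicecov_grid_mismatch")
  }
  if (is.null(dynamic_range)) {
    dynamic_range <- max(max(image_a), max(image_b)) - min(min(image_a), min(image_b))
    dynamic_range <- max(dynamic_range, 1e-8)
  }
  s <- if (length(dim(image_a)) == 3L) {
    mean(vapply(seq_len(dim(image_a)[3]), function(k) {
      ssim2d(image_a[, , k], image_b[, , k], dynamic_range)
    }, numeric(1)))
  } else {
    ssim2d(as.matrix(image_a), as.matrix(image_b), dynamic_range)
  }
  d <- as.numeric(image_a) - as.numeric(image_b)
  tibble::tibble(ssim = s, standard_error = stats::sd(d) / sqrt(length(d)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-normalized band matrix applying a truncated Gaussian along one axis;
# edge windows renormalize so constants are preserved exactly.
gaussian_band_matrix <- function(n, sigma, half = 5L) {
  offs <- (-half):half
  w <- exp(-offs^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (t in seq_along(offs)) {
    j <- seq_len(n) + offs[t]
    ok <- j >= 1 & j <= n
    M[cbind(which(ok), j[ok])] <- M[cbind(which(ok), j[ok])] + w[t]
  }
  M / rowSums(M)
}

# Local-window SSIM on matrices via separable Gaussian moments (sd 1.5,
# 11x11 support), mean-pooled over the image.
ssim2d <- function(a, b, L) {
  Gr <- gaussian_band_matrix(nrow(a), 1.5)
  Gc <- gaussian_band_matrix(ncol(a), 1.5)
  smooth <- function(x) Gr %*% x %*% t(Gc)
  mu_a <- smooth(a); mu_b <- smooth(b)
  va <- smooth(a * a) - mu_a^2
  vb <- smooth(b * b) - mu_b^2
  vab <- smooth(a * b) - mu_a * mu_b
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  num <- (2 * mu_a * mu_b + C1) * (2 * vab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}
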