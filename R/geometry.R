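# Analytic geometry used by the phantom generator and as an independent
# cross-check for voxel-counted overlap.

#' Exact intersection volume of two spheres
#'
#' Closed-form lens (double spherical cap) volume for spheres of radii `r1`
#' and `r2` whose centers are `d` apart. Serves as the analytic reference
#' against which voxel-counted overlap of spherical phantoms is validated.
#'
#' @param r1,r2 Sphere radii (same length unit).
#' @param d Center-to-center distance, >= 0.
#' @return Intersection volume in the cube of the input unit.
#' @export
#' @examples
#' sphere_intersection_volume(20, 25, 10) # mm^3
sphere_intersection_volume <- function(r1, r2, d) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    r <- min(r1, r2)
    return(4 / 3 * pi * r^3)
  }
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) + 6 * r1 * r2 - 3 * r1^2 - 3 * r2^2) / (12 * d)
}

# Voxel-center coordinate vectors (mm) along each axis of a grid.
grid_axes_mm <- function(grid_shape, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(grid_shape[a]) - 0.5) * spacing[a])
}

# Binary ellipsoid mask sampled at voxel centers. center/radii in mm.
ellipsoid_mask_array <- function(grid_shape, spacing, center, radii,
                                 origin = c(0, 0, 0)) {
  ax <- grid_axes_mm(grid_shape, spacing, origin)
  u1 <- ((ax[[1]] - center[1]) / radii[1])^2
  u2 <- ((ax[[2]] - center[2]) / radii[2])^2
  u3 <- ((ax[[3]] - center[3]) / radii[3])^2
  q <- outer(outer(u1, u2, `+`), u3, `+`)
  q <= 1
}

# Does an ellipsoid (center, radii, mm) fit inside the physical grid?
ellipsoid_fits <- function(grid_shape, spacing, center, radii,
                           origin = c(0, 0, 0), margin_mm = 0) {
  extent <- origin + grid_shape * spacing
  all(center - radii >= origin + margin_mm) &&
    all(center + radii <= extent - margin_mm)
}
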