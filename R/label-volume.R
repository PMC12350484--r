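#' Create a label volume (3D binary mask with physical spacing)
#'
#' A `label_volume` is the geometric substrate for coverage computations: a
#' 3D logical array plus the voxel spacing in mm and a physical origin. The
#' third array index is the axial (slice) direction. Voxel `(i, j, k)`
#' (1-based) occupies the half-open box
#' `origin + ((i,j,k) - 1) * spacing` to `origin + (i,j,k) * spacing`,
#' with its center at `origin + ((i,j,k) - 0.5) * spacing`.
#'
#' @param mask 3D array, coerced to logical. Anything non-zero is foreground.
#' @param spacing Numeric length 3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length 3, mm coordinates of the corner of voxel
#'   `(1,1,1)`. Default `c(0, 0, 0)`.
#' @return An object of class `label_volume`.
#' @export
#' @examples
#' m <- array(FALSE, c(8, 8, 4)); m[3:6, 3:6, 2:3] <- TRUE
#' lv <- label_volume(m, spacing = c(1.5, 1.5, 5))
#' mask_volume_cm3(lv)
label_volume <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) {
    stop_slicecov("`mask` must be a 3D array.", "slicecov_bad_mask")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_slicecov("`spacing` must be 3 strictly positive mm values.",
                  "slicecov_bad_spacing")
  }
  structure(
    list(mask = array(as.logical(mask), dim(mask)),
         spacing = spacing,
         origin = as.numeric(origin)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$mask), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$mask), " foreground voxels\n", sep = "")
  invisible(x)
}

is_label_volume <- function(x) inherits(x, "label_volume")

#' Physical volume of a mask in cubic centimeters
#'
#' @param x A [label_volume()].
#' @return Foreground voxel count times voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(x) {
  stopifnot(is_label_volume(x))
  sum(x$mask) * prod(x$spacing) / 1000
}

same_grid <- function(a, b) {
  identical(dim(a$mask), dim(b$mask)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop_slicecov(
      "Masks are on different grids (shape or spacing differ); resample onto a common grid first.",
      "slicecov_grid_mismatch"
    )
  }
  invisible(TRUE)
}

#' Read a binary mask from a NIfTI file
#'
#' Spacing is taken from the NIfTI `pixdim` header; voxels > 0.5 are
#' foreground (robust to masks saved as 0/1 floats).
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D mask.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop_slicecov("Expected a 3D NIfTI image.", "slicecov_bad_mask")
  }
  label_volume(array(img > 0.5, dim(img)), spacing = RNifti::pixdim(img))
}

#' Write a label volume or intensity volume to NIfTI
#'
#' @param x A [label_volume()] or a 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing mm spacing, required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL) {
  if (is_label_volume(x)) {
    arr <- array(as.numeric(x$mask), dim(x$mask))
    spacing <- x$spacing
  } else {
    if (is.null(spacing)) {
      stop_slicecov("`spacing` is required for bare arrays.", "slicecov_bad_spacing")
    }
    arr <- x
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
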