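#' Construct a standardized slice image
#'
#' A `slice_image` carries a square, `[0, 1]`-normalized pixel grid plus
#' provenance: which case and ROI it came from, which axial index was
#' extracted, and the intensity window applied. The canonical size produced
#' by [crop_pad_center()] is 300 x 300.
#'
#' @param pixels Square numeric matrix with values in `[0, 1]`.
#' @param case_id Case identifier.
#' @param roi_kind `"tumor"` or `"ablation"`.
#' @param slice_index 1-based axial index the slice was taken from.
#' @param window Length-2 numeric `(low, high)` intensity window used.
#' @param aug `"original"` or `"noise"`; augmentation provenance tag.
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, case_id = NA_character_,
                        roi_kind = c("tumor", "ablation"),
                        slice_index = NA_integer_,
                        window = c(NA_real_, NA_real_),
                        aug = "original") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) {
    stop_slicecov("`pixels` must be square.", "slicecov_bad_slice")
  }
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop_slicecov("`pixels` must be normalized to [0, 1].", "slicecov_bad_slice")
  }
  roi_kind <- match.arg(roi_kind)
  structure(
    list(pixels = pixels, case_id = case_id, roi_kind = roi_kind,
         slice_index = as.integer(slice_index), window = as.numeric(window),
         aug = aug),
    class = "slice_image"
  )
}

#' @export
print.slice_image <- function(x, ...) {
  cat("<slice_image> ", x$case_id, "/", x$roi_kind, " (", x$aug, "), ",
      nrow(x$pixels), "x", ncol(x$pixels), " px, axial index ",
      x$slice_index, "\n", sep = "")
  invisible(x)
}

#' ROI isocenter of a binary mask
#'
#' Voxel coordinates of the mask's 3D center of mass, rounded half away
#' from zero to integers. The centroid is used rather than the maximal-area
#' slice because it is stable for concave shapes; see [extract_center_slice()]
#' for the max-area alternative.
#'
#' @param mask A [label_volume()]; must be nonempty.
#' @return Integer vector `(i, j, k)` of 1-based voxel indices.
#' @export
roi_isocenter <- function(mask) {
  stopifnot(is_label_volume(mask))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_slicecov("Mask is empty; it has no isocenter.", "slicecov_empty_mask")
  }
  as.integer(round_half_up(colMeans(idx)))
}

#' Extract the axial slice through the ROI isocenter
#'
#' @param volume 3D numeric array sharing the mask's grid.
#' @param mask A nonempty [label_volume()] identifying the ROI.
#' @param method `"centroid"` (default; axial index of the 3D center of
#'   mass) or `"max_area"` (axial index with the largest in-plane ROI area).
#' @return List with `pixels` (2D matrix `volume[, , k]`), `slice_index`
#'   (the chosen `k`) and `center_ij` (in-plane ROI centroid on that
#'   convention, for downstream cropping).
#' @export
extract_center_slice <- function(volume, mask, method = c("centroid", "max_area")) {
  method <- match.arg(method)
  stopifnot(is_label_volume(mask))
  if (!identical(dim(volume), dim(mask$mask))) {
    stop_slicecov("Volume and mask grids differ.", "slicecov_grid_mismatch")
  }
  iso <- roi_isocenter(mask)
  k <- if (method == "centroid") {
    iso[3]
  } else {
    areas <- apply(mask$mask, 3, sum)
    which.max(areas)
  }
  list(pixels = volume[, , k], slice_index = as.integer(k),
       center_ij = iso[1:2])
}

#' Center-crop (and pad) a slice to a fixed square size
#'
#' Output pixel `(r, c)` reads input pixel
#' `(center_ij[1] + r - half, center_ij[2] + c - half)` with
#' `half = floor(size / 2) + 1`, i.e. the requested center lands on output
#' index `floor(size / 2) + 1` (left-biased for even sizes: index 151 of a
#' 300-wide output). Out-of-bounds reads are filled with `pad`, so the call
#' always succeeds regardless of input size or center position.
#'
#' @param pixels 2D numeric matrix (typically already window-normalized).
#' @param center_ij Length-2 integer `(row, col)` crop center in input
#'   coordinates.
#' @param size Output side length in pixels (default 300).
#' @param pad Fill value for out-of-bounds regions; default 0, the window
#'   minimum after normalization.
#' @return `size` x `size` numeric matrix.
#' @export
crop_pad_center <- function(pixels, center_ij, size = 300L, pad = 0) {
  pixels <- as.matrix(pixels)
  size <- as.integer(size)
  half <- size %/% 2L + 1L
  rows <- center_ij[1] + seq_len(size) - half
  cols <- center_ij[2] + seq_len(size) - half
  out <- matrix(pad, size, size)
  rok <- rows >= 1 & rows <= nrow(pixels)
  cok <- cols >= 1 & cols <= ncol(pixels)
  if (any(rok) && any(cok)) {
    out[rok, cok] <- pixels[rows[rok], cols[cok]]
  }
  out
}

#' Window and normalize CT intensities to `[0, 1]`
#'
#' Clips intensities to `[low, high]` then maps the window linearly onto
#' `[0, 1]`. The default window `(-160, 240)` pseudo-HU is a soft-tissue
#' window wide enough to keep liver, enhancing tumor and devascularized
#' ablation zone separable.
#'
#' @param pixels Numeric matrix/array of intensities.
#' @param window Length-2 numeric `(low, high)`, `low < high`.
#' @return Same shape as `pixels`, values in `[0, 1]`.
#' @export
window_normalize <- function(pixels, window = c(-160, 240)) {
  if (!is.numeric(window) || length(window) != 2 || !(window[1] < window[2])) {
    stop_slicecov("`window` must be (low, high) with low < high.",
                  "slicecov_bad_window")
  }
  (clip(pixels, window[1], window[2]) - window[1]) / (window[2] - window[1])
}

#' Extract the standardized isocenter slice for one ROI of a case
#'
#' Convenience composition used throughout the pipeline: pick the axial
#' isocenter slice of the ROI, window-normalize it, then center-crop/pad to
#' `size` x `size` around the in-plane ROI centroid.
#'
#' @param volume 3D intensity array.
#' @param mask [label_volume()] for the ROI on the same grid.
#' @param case_id,roi_kind Provenance recorded on the result.
#' @param window Intensity window, see [window_normalize()].
#' @param size Output side length (default 300).
#' @param method Isocenter convention, see [extract_center_slice()].
#' @return A [slice_image()].
#' @export
standardized_roi_slice <- function(volume, mask, case_id, roi_kind,
                                   window = c(-160, 240), size = 300L,
                                   method = "centroid") {
  ext <- extract_center_slice(volume, mask, method = method)
  norm <- window_normalize(ext$pixels, window)
  slice_image(crop_pad_center(norm, ext$center_ij, size = size, pad = 0),
              case_id = case_id, roi_kind = roi_kind,
              slice_index = ext$slice_index, window = window)
}
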