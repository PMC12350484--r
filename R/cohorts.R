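#' Gaussian-noise augmentation of a slice
#'
#' Adds i.i.d. Gaussian noise (non-zero mean, small variance) to a
#' normalized slice and clips back to `[0, 1]`. Defaults are mean 0.01 and
#' variance 0.001 on the `[0, 1]` intensity scale. Deterministic per seed.
#'
#' @param slice A [slice_image()] (or plain matrix in `[0, 1]`).
#' @param mean Noise mean (intensity units).
#' @param variance Noise variance (intensity units squared).
#' @param seed Integer seed for the draw.
#' @return Same type as `slice`, with `aug = "noise"` recorded when the
#'   input is a `slice_image`.
#' @export
add_gaussian_noise <- function(slice, mean = 0.01, variance = 0.001, seed = 1L) {
  px <- if (inherits(slice, "slice_image")) slice$pixels else as.matrix(slice)
  noise <- withr::with_seed(seed, {
    matrix(stats::rnorm(length(px), mean = mean, sd = sqrt(variance)),
           nrow(px), ncol(px))
  })
  out <- clip(px + noise, 0, 1)
  if (inherits(slice, "slice_image")) {
    slice$pixels <- out
    slice$aug <- "noise"
    slice
  } else {
    out
  }
}

#' Rotate a square slice by 90 degrees counter-clockwise
#'
#' Convention: output pixel `(r, c)` reads input pixel `(c, n + 1 - r)`,
#' so four applications are the identity and the pixel multiset is
#' preserved. Implemented as an available augmentation; the canonical
#' noise-augmented cohorts of [build_cohort()] do not use it.
#'
#' @param slice A [slice_image()] or square matrix.
#' @return Same type as `slice`.
#' @export
rotate90 <- function(slice) {
  px <- if (inherits(slice, "slice_image")) slice$pixels else as.matrix(slice)
  if (nrow(px) != ncol(px)) {
    stop_slicecov("Rotation requires a square slice.", "slicecov_bad_slice")
  }
  n <- nrow(px)
  out <- t(px)[n:1, , drop = FALSE]
  if (inherits(slice, "slice_image")) {
    slice$pixels <- out
    slice
  } else {
    out
  }
}

#' Case-level train/test split
#'
#' Randomly assigns whole cases to training or testing so that no case
#' (and therefore no augmented copy of it) appears in both sides. The
#' training size is `round-half-up(ratio * n)`; with 182 cases and the
#' default 80:20 ratio this gives the canonical 146:36.
#'
#' @param case_ids Character/atomic vector of unique case identifiers, n >= 2.
#' @param ratio Training fraction, default 0.8.
#' @param seed Integer seed.
#' @return A tibble with columns `case_id` and `split`
#'   (`"train"`/`"test"`), one row per case, in the input order.
#' @export
#' @examples
#' table(split_cases(sprintf("c%03d", 1:182), seed = 7)$split)
split_cases <- function(case_ids, ratio = 0.8, seed = 1L) {
  n <- length(case_ids)
  if (n < 2) {
    stop_slicecov("Need at least 2 cases to split.", "slicecov_config_error")
  }
  if (anyDuplicated(case_ids)) {
    stop_slicecov("`case_ids` must be unique.", "slicecov_config_error")
  }
  n_train <- as.integer(round_half_up(ratio * n))
  train_idx <- withr::with_seed(seed, sample.int(n, n_train))
  tibble::tibble(
    case_id = case_ids,
    split = ifelse(seq_len(n) %in% train_idx, "train", "test")
  )
}

#' Pair the tumor and ablation slices of generated cases
#'
#' Builds the tibble of original (un-augmented) case pairs that
#' [build_cohort()] expands: one row per case with both standardized
#' slices and the ground-truth coverage label.
#'
#' @param cases List of `phantom_case` objects (or anything with
#'   `pre_volume`, `post_volume`, `tumor_mask`, `ablation_mask`,
#'   `true_coverage`, `case_id`).
#' @param window Intensity window for [standardized_roi_slice()].
#' @param size Slice side length.
#' @return Tibble with columns `case_id`, `coverage`, `tumor_slice`,
#'   `ablation_slice` (list-columns of [slice_image()]).
#' @export
make_case_pairs <- function(cases, window = c(-160, 240), size = 300L) {
  rows <- purrr::map(cases, function(cs) {
    tibble::tibble(
      case_id = cs$case_id,
      coverage = cs$true_coverage,
      tumor_slice = list(standardized_roi_slice(
        cs$pre_volume, cs$tumor_mask, cs$case_id, "tumor",
        window = window, size = size)),
      ablation_slice = list(standardized_roi_slice(
        cs$post_volume, cs$ablation_mask, cs$case_id, "ablation",
        window = window, size = size))
    )
  })
  dplyr::bind_rows(rows)
}

#' Expand original case pairs into an augmentation cohort
#'
#' Three canonical cohorts of increasing size:
#' * level 1 — originals only: one `(original, original)` pair per case (n pairs);
#' * level 2 — noise added, exclusively paired: `(original, original)` and
#'   `(noise, noise)` (2n pairs);
#' * level 3 — crossed: all four combinations of original/noise tumor and
#'   ablation slices (4n pairs).
#'
#' One noise realization is drawn per case and ROI (sub-seed derived from
#' the case id), and reused across the level-3 pairings, so the four
#' combinations of a case share the same noised images. The coverage label
#' is copied unchanged to every augmented pair. Augmentation happens after
#' (and independently of) the case-level split, so expanding a cohort can
#' never leak a case across the split.
#'
#' @param pairs Tibble from [make_case_pairs()]: one original pair per case.
#' @param level Augmentation level, 1, 2 or 3.
#' @param seed Integer seed for the noise draws.
#' @param noise_mean,noise_variance Parameters of [add_gaussian_noise()].
#' @return Tibble with columns `case_id`, `coverage`, `aug_tumor`,
#'   `aug_ablation` (`"original"`/`"noise"`), `tumor_slice`,
#'   `ablation_slice`; n, 2n or 4n rows.
#' @export
build_cohort <- function(pairs, level, seed = 1L,
                         noise_mean = 0.01, noise_variance = 0.001) {
  if (!level %in% 1:3) {
    stop_slicecov("`level` must be 1, 2 or 3.", "slicecov_config_error")
  }
  if (anyDuplicated(pairs$case_id)) {
    stop_slicecov("`pairs` must hold one original pair per case.",
                  "slicecov_config_error")
  }
  combos <- list(
    list(c("original", "original")),
    list(c("original", "original"), c("noise", "noise")),
    list(c("original", "original"), c("original", "noise"),
         c("noise", "original"), c("noise", "noise"))
  )[[as.integer(level)]]
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    cid <- pairs$case_id[i]
    orig_t <- pairs$tumor_slice[[i]]
    orig_a <- pairs$ablation_slice[[i]]
    needs_noise <- level >= 2
    noise_t <- if (needs_noise) {
      add_gaussian_noise(orig_t, noise_mean, noise_variance,
                         seed = sub_seed(seed, "noise", cid, "tumor"))
    }
    noise_a <- if (needs_noise) {
      add_gaussian_noise(orig_a, noise_mean, noise_variance,
                         seed = sub_seed(seed, "noise", cid, "ablation"))
    }
    pick <- function(tag, orig, noised) if (tag == "noise") noised else orig
    dplyr::bind_rows(lapply(combos, function(cmb) {
      tibble::tibble(
        case_id = cid, coverage = pairs$coverage[i],
        aug_tumor = cmb[1], aug_ablation = cmb[2],
        tumor_slice = list(pick(cmb[1], orig_t, noise_t)),
        ablation_slice = list(pick(cmb[2], orig_a, noise_a)))
    }))
  })
  dplyr::bind_rows(rows)
}
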