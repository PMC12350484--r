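# Deep-feature extraction: a slice image is standardized to a 224x224x3
# tensor, pushed through a convolutional backbone, and flattened; paired
# slices are compared by element-wise feature differencing.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Standardize a slice for a convolutional backbone
#'
#' Bilinearly resizes the `[0, 1]` slice to 224 x 224, replicates the gray
#' channel to 3 channels, and standardizes each channel with the
#' conventional ImageNet statistics (means 0.485/0.456/0.406, sds
#' 0.229/0.224/0.225) — the input contract of VGG-style backbones.
#'
#' @param slice A [slice_image()] or square matrix with values in `[0, 1]`.
#' @param size Output spatial size (default 224).
#' @return A `size` x `size` x 3 numeric array.
#' @export
preprocess_for_backbone <- function(slice, size = 224L) {
  px <- if (inherits(slice, "slice_image")) slice$pixels else as.matrix(slice)
  if (nrow(px) != ncol(px)) {
    stop_slicecov("Backbone preprocessing expects a square slice.",
                  "slicecov_bad_slice")
  }
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9) {
    stop_slicecov("Slice must be normalized to [0, 1] before preprocessing.",
                  "slicecov_bad_slice")
  }
  resized <- if (nrow(px) == size) px else EBImage::resize(px, w = size, h = size)
  resized <- clip(resized, 0, 1)
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    out[, , ch] <- (resized - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
  }
  out
}

# ---- minimal conv-net plumbing (3x3 'same' convs, ReLU, 2x2 max pool) ----

# im2col for 3x3 same-padded convolution: (H*W) x (9*C) patch matrix.
# Column order: offset-major, then input channel; weights use the same order.
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  padded <- array(0, c(H + 2, W + 2, C))
  padded[2:(H + 1), 2:(W + 1), ] <- x
  cols <- vector("list", 9L)
  t <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      t <- t + 1L
      block <- padded[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
      dim(block) <- c(H * W, C)
      cols[[t]] <- block
    }
  }
  do.call(cbind, cols)
}

conv3x3 <- function(x, weights, bias = NULL, relu = TRUE) {
  d <- dim(x)
  out <- im2col3(x) %*% weights
  if (!is.null(bias)) out <- sweep(out, 2, bias, `+`)
  if (relu) out <- pmax(out, 0)
  dim(out) <- c(d[1], d[2], ncol(weights))
  out
}

maxpool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1] - 1, by = 2); j1 <- seq(1, d[2] - 1, by = 2)
  pmax(x[i1, j1, , drop = FALSE], x[i1 + 1, j1, , drop = FALSE],
       x[i1, j1 + 1, , drop = FALSE], x[i1 + 1, j1 + 1, , drop = FALSE])
}

avgpool <- function(x, k) {
  d <- dim(x)
  out <- 0
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      out <- out + x[seq(di, d[1], by = k), seq(dj, d[2], by = k), , drop = FALSE]
    }
  }
  out / k^2
}

# He-initialized 3x3 conv weight matrix (9*in x out), deterministic per seed.
he_conv_weights <- function(in_ch, out_ch, seed) {
  withr::with_seed(seed, {
    matrix(stats::rnorm(9 * in_ch * out_ch, sd = sqrt(2 / (9 * in_ch))),
           nrow = 9 * in_ch, ncol = out_ch)
  })
}

# ---- extractor backends ----

VGG16_PLAN <- list(
  c(64, 64), c(128, 128), c(256, 256, 256), c(512, 512, 512), c(512, 512, 512))

#' VGG16-flatten feature extractor
#'
#' Instantiates the VGG16 convolutional architecture (thirteen 3x3
#' same-padded convolutions with ReLU in five blocks of 64/128/256/512/512
#' channels, each block followed by 2x2 max pooling) and reads features at
#' the flatten layer: a 224 x 224 x 3 input yields `512 * 7 * 7 = 25088`
#' features. With `weights = NULL` the convolution kernels are
#' He-initialized from `seed` — the architecture's shape, receptive fields
#' and feature dimensionality are exact, while the filters are random
#' rather than ImageNet-trained. A list of pretrained kernel matrices (one
#' `9*C_in x C_out` matrix per convolution, im2col layout) can be supplied
#' via `weights` for fidelity runs; requesting a weights file that does not
#' exist raises an explicit capability error suggesting the random-weight
#' or [randconv_extractor()] fallback.
#'
#' @param weights `NULL` (He-initialized from `seed`), a list of 13 kernel
#'   matrices, or a path to an `.rds` holding such a list.
#' @param seed Seed for the He initialization.
#' @return A `feature_extractor` object (class `vgg16_extractor`).
#' @export
vgg16_extractor <- function(weights = NULL, seed = 2016L) {
  chans <- unlist(VGG16_PLAN)
  ins <- c(3, head(chans, -1))
  if (is.character(weights)) {
    if (!file.exists(weights)) {
      stop_slicecov(
        paste0("Pretrained VGG16 weights not found at '", weights,
               "'. Use weights = NULL (random init) or randconv_extractor()."),
        "slicecov_capability_error")
    }
    weights <- readRDS(weights)
  }
  if (is.null(weights)) {
    weights <- lapply(seq_along(chans), function(l) {
      he_conv_weights(ins[l], chans[l], seed = sub_seed(seed, "vgg16-layer", l))
    })
    id <- paste0("vgg16-flatten-randinit-", seed)
  } else {
    id <- "vgg16-flatten-pretrained"
  }
  stopifnot(length(weights) == length(chans))
  structure(
    list(id = id, dim = 25088L, weights = weights, plan = VGG16_PLAN),
    class = c("vgg16_extractor", "feature_extractor"))
}

#' Random-convolution fallback feature extractor
#'
#' A weight-free-to-obtain, fully deterministic backbone for pipelines that
#' must run without any downloaded weights: 2x2 average pooling to
#' 112 x 112 (gentle enough to keep pixel-scale landmark shifts, which are
#' what distinguish neighbouring axial planes), then three He-initialized
#' 3x3 convolution + ReLU + 2x2 max-pool stages (3 to 32 to 128 to 128
#' channels), flattened at 14 x 14 x 128 — the same 25,088-length output
#' as the VGG16 flatten layer but on a twice-finer spatial grid, at a
#' small fraction of the compute. Random convolutional features preserve local image
#' structure, so slices from nearby axial planes remain closer in feature
#' space than distant ones, which is the property the coverage predictors
#' rely on.
#'
#' @param seed Seed for the He initialization; part of the extractor id.
#' @return A `feature_extractor` object (class `randconv_extractor`).
#' @export
randconv_extractor <- function(seed = 2024L) {
  chans <- c(32, 128, 128)
  ins <- c(3, head(chans, -1))
  weights <- lapply(seq_along(chans), function(l) {
    he_conv_weights(ins[l], chans[l], seed = sub_seed(seed, "randconv-layer", l))
  })
  structure(
    list(id = paste0("randconv-", seed), dim = 25088L, weights = weights),
    class = c("randconv_extractor", "feature_extractor"))
}

#' Extract a flattened feature vector from a preprocessed image
#'
#' @param extractor A [vgg16_extractor()] or [randconv_extractor()].
#' @param image A 224 x 224 x 3 array from [preprocess_for_backbone()].
#' @return Numeric feature vector of length `extractor$dim` with attribute
#'   `extractor_id`; identical inputs give identical outputs (the backbones
#'   have no stochastic layers at inference).
#' @export
extract_features <- function(extractor, image) {
  UseMethod("extract_features")
}

check_backbone_input <- function(image) {
  if (!identical(dim(image), c(224L, 224L, 3L)) &&
      !identical(dim(image), c(224, 224, 3))) {
    stop_slicecov("Backbone input must be a 224 x 224 x 3 array.",
                  "slicecov_bad_input")
  }
}

#' @export
extract_features.vgg16_extractor <- function(extractor, image) {
  check_backbone_input(image)
  x <- image
  l <- 0L
  for (block in extractor$plan) {
    for (ch in block) {
      l <- l + 1L
      x <- conv3x3(x, extractor$weights[[l]])
    }
    x <- maxpool2(x)
  }
  as_feature_vector(x, extractor)
}

#' @export
extract_features.randconv_extractor <- function(extractor, image) {
  check_backbone_input(image)
  x <- avgpool(image, 2L)
  for (w in extractor$weights) {
    x <- maxpool2(conv3x3(x, w))
  }
  as_feature_vector(x, extractor)
}

as_feature_vector <- function(x, extractor) {
  v <- as.numeric(x)
  stopifnot(length(v) == extractor$dim)
  attr(v, "extractor_id") <- extractor$id
  v
}

#' Element-wise feature difference of a slice pair
#'
#' The model input of the slice-based estimator: `tumor - ablation`,
#' element-wise, between two feature vectors from the same extractor. The
#' order is fixed (tumor first) so the sign convention is consistent across
#' the cohort.
#'
#' @param f_tumor,f_ablation Feature vectors from [extract_features()],
#'   same extractor and length.
#' @return Numeric difference vector with the `extractor_id` attribute.
#' @export
feature_difference <- function(f_tumor, f_ablation) {
  if (length(f_tumor) != length(f_ablation)) {
    stop_slicecov("Feature vectors have different lengths.",
                  "slicecov_dim_mismatch")
  }
  id_t <- attr(f_tumor, "extractor_id")
  id_a <- attr(f_ablation, "extractor_id")
  if (!is.null(id_t) && !is.null(id_a) && !identical(id_t, id_a)) {
    stop_slicecov("Feature vectors come from different extractors.",
                  "slicecov_dim_mismatch")
  }
  d <- as.numeric(f_tumor) - as.numeric(f_ablation)
  attr(d, "extractor_id") <- id_t
  d
}

#' Difference-vector matrix for a cohort of slice pairs
#'
#' Runs the extractor over every distinct slice of a [build_cohort()]
#' tibble (caching by case, ROI and augmentation tag so a slice shared by
#' several level-3 pairings is featurized once) and stacks the
#' tumor-minus-ablation difference vectors row-wise.
#'
#' @param cohort Tibble from [build_cohort()].
#' @param extractor A `feature_extractor`.
#' @return Numeric matrix, `nrow(cohort)` x `extractor$dim`, rows aligned
#'   with `cohort`.
#' @export
cohort_difference_matrix <- function(cohort, extractor) {
  cache <- new.env(parent = emptyenv())
  feat_of <- function(slice) {
    key <- paste(slice$case_id, slice$roi_kind, slice$aug, sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- extract_features(extractor, preprocess_for_backbone(slice))
    }
    cache[[key]]
  }
  out <- matrix(0, nrow(cohort), extractor$dim)
  for (i in seq_len(nrow(cohort))) {
    out[i, ] <- feature_difference(feat_of(cohort$tumor_slice[[i]]),
                                   feat_of(cohort$ablation_slice[[i]]))
  }
  colnames(out) <- paste0("d", seq_len(ncol(out)))
  out
}
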