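# Prediction heads on difference vectors: a voting random-forest
# classifier over four clinically meaningful coverage bins, and
# random-forest / neural-network regressors of percent coverage.

#' Coverage class levels
#'
#' The four ordinal tumor-coverage bins: `<=50` (incomplete), `50-70`
#' (partially incomplete), `70-90` (acceptable), `>=90` (complete).
#'
#' @return Character vector of the four level names, in order.
#' @export
coverage_class_levels <- function() c("<=50", "50-70", "70-90", ">=90")

#' Map percent coverage to its ordinal class
#'
#' Bin convention: `<=50` is `[0, 50]`, `50-70` is `(50, 70)`, `70-90` is
#' `[70, 90)`, `>=90` is `[90, 100]` — the outer bins take their stated
#' boundary values literally; 70 is assigned upward and 90 to the top bin.
#'
#' @param coverage Numeric percent coverage(s) in `[0, 100]`.
#' @return Ordered factor over [coverage_class_levels()].
#' @export
#' @examples
#' class_of(c(50, 65, 70, 90, 99))
class_of <- function(coverage) {
  if (any(!is.finite(coverage)) || any(coverage < 0 | coverage > 100)) {
    stop_slicecov("`coverage` must lie in [0, 100].", "slicecov_domain_error")
  }
  lv <- coverage_class_levels()
  idx <- ifelse(coverage <= 50, 1L,
                ifelse(coverage < 70, 2L,
                       ifelse(coverage < 90, 3L, 4L)))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

check_feature_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("d", seq_len(ncol(x)))
  x
}

#' Train the coverage-class random forest
#'
#' Fits a 100-tree random forest on difference vectors; class predictions
#' are made by voting across trees ([predict_class()] exposes the per-class
#' vote fractions). Remaining hyperparameters stay at the forest library's
#' defaults and are recorded in the returned object.
#'
#' @param x Numeric matrix of difference vectors (rows = pairs).
#' @param y Coverage classes: a factor over [coverage_class_levels()] or
#'   numeric coverages (converted with [class_of()]). At least two classes
#'   must be present.
#' @param seed Integer; the fit is reproducible per seed.
#' @param num_trees Number of trees (default 100).
#' @return Object of class `coverage_classifier` with the fitted forest,
#'   the class set, training class priors and metadata.
#' @export
train_classifier <- function(x, y, seed = 1L, num_trees = 100L) {
  x <- check_feature_matrix(x)
  if (is.numeric(y)) y <- class_of(y)
  y <- factor(y, levels = coverage_class_levels())
  if (length(unique(y[!is.na(y)])) < 2) {
    stop_slicecov("Training set holds a single class; cannot fit a classifier.",
                  "slicecov_degenerate_training")
  }
  fit <- ranger::ranger(x = x, y = factor(y), num.trees = num_trees,
                        seed = seed, num.threads = 1)
  structure(
    list(fit = fit, classes = coverage_class_levels(),
         priors = as.numeric(table(y)) / length(y),
         feature_names = colnames(x),
         num_trees = num_trees, seed = seed),
    class = "coverage_classifier")
}

as_model_matrix <- function(x, feature_names) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(feature_names)) {
    stop_slicecov("Feature dimension does not match the model.",
                  "slicecov_dim_mismatch")
  }
  colnames(x) <- feature_names
  x
}

#' Predict coverage classes by tree voting
#'
#' Each tree votes for a class; the prediction is the class with the
#' largest vote fraction, ties broken toward the lower (worse-coverage)
#' class — the conservative choice for a treatment-completeness flag.
#'
#' @param model A [train_classifier()] fit.
#' @param x Difference-vector matrix (or a single vector).
#' @return Tibble with `class_pred` and one `vote_<class>` fraction column
#'   per class; fractions are nonnegative and sum to 1 in every row.
#' @export
predict_class <- function(model, x) {
  stopifnot(inherits(model, "coverage_classifier"))
  x <- as_model_matrix(x, model$feature_names)
  pa <- stats::predict(model$fit, data = x, predict.all = TRUE,
                       num.threads = 1)$predictions
  if (is.null(dim(pa))) pa <- matrix(pa, nrow = 1)
  trained_levels <- model$fit$forest$levels
  votes <- matrix(0, nrow(pa), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (ci in seq_along(trained_levels)) {
    votes[, trained_levels[ci]] <- rowMeans(pa == ci)
  }
  pred_idx <- apply(votes, 1, which.max) # first max = lower class on ties
  out <- tibble::as_tibble(as.data.frame(votes, check.names = FALSE))
  names(out) <- paste0("vote_", model$classes)
  dplyr::bind_cols(
    tibble::tibble(class_pred = factor(model$classes[pred_idx],
                                       levels = model$classes, ordered = TRUE)),
    out)
}

#' Train a coverage regressor (random forest or neural network)
#'
#' Two variants mirror common practice on flattened deep features:
#' * `"rf"` — a 100-tree random forest (library defaults otherwise);
#' * `"dnn"` — a fully connected network with ReLU hidden layers of 4096
#'   and 1024 units and a linear output, trained for exactly 30 epochs with
#'   Adam (learning rate 1e-4, batch size 16) on mean-squared error.
#'   Inputs and targets are standardized internally (predictions are
#'   returned on the percent scale); the per-epoch training loss is
#'   recorded (on the standardized scale) and a smoothed-monotone
#'   convergence flag is stored.
#'
#' @param x Difference-vector matrix.
#' @param y Numeric percent coverages.
#' @param variant `"rf"` or `"dnn"`.
#' @param seed Integer seed; fits are reproducible per seed.
#' @param num_trees Trees for the forest variant (default 100).
#' @param hidden Hidden layer widths for the DNN (default `c(4096, 1024)`).
#' @param epochs,batch_size,lr DNN training schedule (defaults 30, 16, 1e-4).
#' @return Object of class `coverage_regressor`; predictions from
#'   [predict_coverage()] are clamped to at most 100.
#' @export
train_regressor <- function(x, y, variant = c("rf", "dnn"), seed = 1L,
                            num_trees = 100L, hidden = c(4096L, 1024L),
                            epochs = 30L, batch_size = 16L, lr = 1e-4) {
  variant <- match.arg(variant)
  x <- check_feature_matrix(x)
  y <- as.numeric(y)
  if (length(y) < 2 || nrow(x) != length(y)) {
    stop_slicecov("Need >= 2 aligned samples to train a regressor.",
                  "slicecov_degenerate_training")
  }
  fit <- if (variant == "rf") {
    ranger::ranger(x = x, y = y, num.trees = num_trees,
                   seed = seed, num.threads = 1)
  } else {
    mlp_train(x, y, hidden = hidden, epochs = epochs,
              batch_size = batch_size, lr = lr, seed = seed)
  }
  structure(
    list(variant = variant, fit = fit, feature_names = colnames(x),
         clamp_max = 100, seed = seed,
         loss_history = if (variant == "dnn") fit$loss_history,
         converged = if (variant == "dnn") fit$converged else NA),
    class = "coverage_regressor")
}

#' Predict percent coverage from difference vectors
#'
#' Raw model output capped at 100% (a tumor cannot be more than fully
#' covered); no lower clamp is applied.
#'
#' @param model A [train_regressor()] fit.
#' @param x Difference-vector matrix (or a single vector).
#' @return Numeric vector of predicted percent coverages, each <= 100.
#' @export
predict_coverage <- function(model, x) {
  stopifnot(inherits(model, "coverage_regressor"))
  x <- as_model_matrix(x, model$feature_names)
  raw <- if (model$variant == "rf") {
    stats::predict(model$fit, data = x, num.threads = 1)$predictions
  } else {
    mlp_predict(model$fit, x)
  }
  pmin(as.numeric(raw), model$clamp_max)
}

# ---- fully connected network, trained with Adam on MSE ----

mlp_train <- function(x, y, hidden, epochs, batch_size, lr, seed,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(x)
  y_center <- mean(y)
  y_scale <- max(stats::sd(y), 1e-8)
  y <- (y - y_center) / y_scale
  x_center <- colMeans(x)
  x_scale <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  params <- withr::with_seed(sub_seed(seed, "mlp-init"), {
    lapply(seq_len(L), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                   sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
  mom <- lapply(params, function(p) {
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
  step <- 0L
  loss_history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    ord <- withr::with_seed(sub_seed(seed, "mlp-epoch", epoch), sample.int(n))
    batch_losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1, n)]
      xb <- xs[rows, , drop = FALSE]
      yb <- y[rows]
      acts <- list(xb)
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`)
        acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
      }
      pred <- acts[[L + 1]][, 1]
      err <- pred - yb
      batch_losses <- c(batch_losses, mean(err^2))
      delta <- matrix(2 * err / length(err), ncol = 1)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
        }
        mom[[l]]$mW <- beta1 * mom[[l]]$mW + (1 - beta1) * gW
        mom[[l]]$vW <- beta2 * mom[[l]]$vW + (1 - beta2) * gW^2
        mom[[l]]$mb <- beta1 * mom[[l]]$mb + (1 - beta1) * gb
        mom[[l]]$vb <- beta2 * mom[[l]]$vb + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step
        corr2 <- 1 - beta2^step
        params[[l]]$W <- params[[l]]$W -
          lr * (mom[[l]]$mW / corr1) / (sqrt(mom[[l]]$vW / corr2) + eps)
        params[[l]]$b <- params[[l]]$b -
          lr * (mom[[l]]$mb / corr1) / (sqrt(mom[[l]]$vb / corr2) + eps)
      }
    }
    loss_history[epoch] <- mean(batch_losses)
  }
  smoothed <- stats::filter(loss_history, rep(1 / 5, 5), sides = 1)
  smoothed <- smoothed[!is.na(smoothed)]
  list(params = params, x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale,
       sizes = sizes, loss_history = loss_history,
       converged = all(diff(smoothed) <= 1e-6))
}

mlp_predict <- function(fit, x) {
  xs <- sweep(sweep(as.matrix(x), 2, fit$x_center), 2, fit$x_scale, `/`)
  L <- length(fit$params)
  a <- xs
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$params[[l]]$W, 2, fit$params[[l]]$b, `+`)
    a <- if (l < L) pmax(z, 0) else z
  }
  fit$y_center + fit$y_scale * a[, 1]
}
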