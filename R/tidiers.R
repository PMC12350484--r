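# broom-style tidiers for report and model objects.

#' Tidy a classification report
#'
#' @param x A [classification_report()].
#' @param ... Unused.
#' @return Per-class tibble: `class`, `n`, `tpr`, `tnr`, `auc`.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' One-row summary of a classification report
#'
#' @param x A [classification_report()].
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `macro_auc`, `macro_tpr`, `macro_tnr`.
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, macro_auc = x$macro_auc,
                 macro_tpr = x$macro_tpr, macro_tnr = x$macro_tnr)
}

#' Tidy a regression report (per-case errors)
#'
#' @param x A [regression_report()].
#' @param ... Unused.
#' @return Tibble with `true`, `predicted`, `error`.
#' @method tidy regression_report
#' @export
tidy.regression_report <- function(x, ...) x$data

#' One-row summary of a regression report
#'
#' @param x A [regression_report()].
#' @param ... Unused.
#' @return Tibble with `n`, `mse`, `rmse`, `mae`, `pearson_r`,
#'   `spearman_rho`, `ks_p`.
#' @method glance regression_report
#' @export
glance.regression_report <- function(x, ...) {
  tibble::tibble(n = x$n, mse = x$mse, rmse = x$rmse, mae = x$mae,
                 pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
                 ks_p = x$ks_p)
}

#' Tidy a one-vs-rest ROC analysis (curve points)
#'
#' @param x An [one_vs_rest_roc()] result.
#' @param ... Unused.
#' @return Tibble with `class`, `threshold`, `fpr`, `tpr`.
#' @method tidy ovr_roc
#' @export
tidy.ovr_roc <- function(x, ...) x$curves

#' One-row-per-class AUC summary of a one-vs-rest ROC analysis
#'
#' @param x An [one_vs_rest_roc()] result.
#' @param ... Unused.
#' @return The per-class AUC tibble with the macro AUC attached as a column.
#' @method glance ovr_roc
#' @export
glance.ovr_roc <- function(x, ...) {
  dplyr::mutate(x$aucs, macro_auc = x$macro_auc)
}

#' Metadata summary of a fitted coverage classifier
#'
#' @param x A [train_classifier()] model.
#' @param ... Unused.
#' @return One-row tibble of model metadata.
#' @method glance coverage_classifier
#' @export
glance.coverage_classifier <- function(x, ...) {
  tibble::tibble(num_trees = x$num_trees, seed = x$seed,
                 n_features = length(x$feature_names),
                 oob_error = x$fit$prediction.error)
}

#' Metadata summary of a fitted coverage regressor
#'
#' @param x A [train_regressor()] model.
#' @param ... Unused.
#' @return One-row tibble of model metadata (variant, seed, convergence
#'   flag and final training loss for the DNN).
#' @method glance coverage_regressor
#' @export
glance.coverage_regressor <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, seed = x$seed,
    n_features = length(x$feature_names),
    converged = x$converged,
    final_train_loss = if (!is.null(x$loss_history)) {
      tail(x$loss_history, 1)
    } else {
      NA_real_
    })
}
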