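# ggplot2 views of the result objects.

#' Plot one-vs-rest ROC curves
#'
#' @param object An [one_vs_rest_roc()] result.
#' @param ... Unused.
#' @return A ggplot: one ROC curve per class plus the chance diagonal.
#' @method autoplot ovr_roc
#' @export
autoplot.ovr_roc <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Coverage class",
                  title = sprintf("One-vs-rest ROC (macro AUC = %.2f)",
                                  object$macro_auc)) +
    ggplot2::theme_minimal()
}

#' Plot a classification report
#'
#' ROC curves when vote fractions were supplied, otherwise a confusion
#' matrix heat map.
#'
#' @param object A [classification_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  if (!is.null(object$roc)) {
    return(autoplot(object$roc))
  }
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Cases",
                  title = sprintf("Accuracy %.1f%%", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot predicted vs true coverage for a regression report
#'
#' @param object A [regression_report()].
#' @param ... Unused.
#' @return A ggplot of predicted against true percent coverage with the
#'   identity line.
#' @method autoplot regression_report
#' @export
autoplot.regression_report <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "True coverage (%)", y = "Predicted coverage (%)",
                  title = sprintf("RMSE %.1f%%, MAE %.1f%%",
                                  object$rmse, object$mae)) +
    ggplot2::theme_minimal()
}

#' Histogram of cohort coverage labels
#'
#' @param cohort A tibble with a `true_coverage` (or `coverage`) column,
#'   e.g. from [generate_cohort()] or [build_cohort()].
#' @param binwidth Histogram bin width in percentage points.
#' @return A ggplot.
#' @export
plot_coverage_distribution <- function(cohort, binwidth = 5) {
  col <- if ("true_coverage" %in% names(cohort)) "true_coverage" else "coverage"
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Percent tumor coverage", y = "Cases") +
    ggplot2::theme_minimal()
}

#' Display a slice image
#'
#' @param x A [slice_image()].
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @method autoplot slice_image
#' @export
autoplot.slice_image <- function(x, ...) {
  # column-major to match as.numeric(matrix): row index varies fastest
  df <- tidyr::expand_grid(col = seq_len(ncol(x$pixels)),
                           row = seq_len(nrow(x$pixels)))
  df$value <- as.numeric(x$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(x$case_id, " / ", x$roi_kind,
                                 " (", x$aug, ")"),
                  x = NULL, y = NULL, fill = "Intensity") +
    ggplot2::theme_minimal()
}
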