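# Statistical evaluation: one-vs-rest ROC analysis for the classifier and
# error/correlation/normality metrics for the regressors.

strip_vote_prefix <- function(m) {
  m <- as.matrix(m)
  colnames(m) <- sub("^vote_", "", colnames(m))
  m
}

#' One-vs-rest ROC analysis of coverage-class scores
#'
#' For each class, dichotomizes the truth into class-vs-rest, scores cases
#' by that class's vote fraction, and computes the ROC curve and its
#' trapezoidal AUC. Classes without at least one positive and one negative
#' case are skipped with a warning. The macro AUC is the unweighted mean
#' over evaluable classes.
#'
#' @param true_classes Factor of true classes (levels define the class set).
#' @param vote_fractions Matrix or data frame of per-class scores, columns
#'   named by class (a `vote_<class>` prefix as produced by
#'   [predict_class()] is accepted).
#' @return Object of class `ovr_roc`: list with `curves` (tibble of class,
#'   threshold, fpr, tpr), `aucs` (tibble of class, auc, n_pos, n_neg) and
#'   `macro_auc`.
#' @export
one_vs_rest_roc <- function(true_classes, vote_fractions) {
  true_classes <- as.factor(true_classes)
  scores <- strip_vote_prefix(vote_fractions)
  if (nrow(scores) != length(true_classes)) {
    stop_slicecov("Scores and labels have different lengths.",
                  "slicecov_length_mismatch")
  }
  classes <- levels(true_classes)
  missing_cols <- setdiff(classes, colnames(scores))
  if (length(missing_cols) > 0) {
    stop_slicecov(paste0("No score column for class(es): ",
                         paste(missing_cols, collapse = ", ")),
                  "slicecov_dim_mismatch")
  }
  curves <- list(); aucs <- list()
  for (cls in classes) {
    pos <- true_classes == cls
    if (sum(pos) == 0 || sum(!pos) == 0) {
      warn(paste0("Class '", cls, "' has no positives or no negatives; skipped."))
      next
    }
    rr <- pROC::roc(response = pos, predictor = scores[, cls],
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    cc <- pROC::coords(rr, "all", ret = c("threshold", "specificity",
                                          "sensitivity"), transpose = FALSE)
    curves[[cls]] <- tibble::tibble(
      class = cls, threshold = cc$threshold,
      fpr = 1 - cc$specificity, tpr = cc$sensitivity)
    aucs[[cls]] <- tibble::tibble(
      class = cls, auc = as.numeric(pROC::auc(rr)),
      n_pos = sum(pos), n_neg = sum(!pos))
  }
  if (length(aucs) == 0) {
    stop_slicecov("No class is evaluable (each lacks positives or negatives).",
                  "slicecov_degenerate_eval")
  }
  aucs <- dplyr::bind_rows(aucs)
  structure(
    list(curves = dplyr::bind_rows(curves), aucs = aucs,
         macro_auc = mean(aucs$auc)),
    class = "ovr_roc")
}

#' @export
print.ovr_roc <- function(x, ...) {
  cat("<ovr_roc> macro AUC ", sprintf("%.3f", x$macro_auc), " over ",
      nrow(x$aucs), " classes\n", sep = "")
  print(x$aucs)
  invisible(x)
}

#' Classification performance report
#'
#' Accuracy (percent of correctly classified cases), the 4x4 confusion
#' matrix, per-class and macro-averaged sensitivity (TPR) and specificity
#' (TNR) from the argmax decision, and — when vote fractions are supplied —
#' the one-vs-rest ROC/AUC analysis. Macro averages are unweighted over the
#' classes that are evaluable for the respective metric.
#'
#' @param true,predicted Aligned factors over the same class levels.
#' @param vote_fractions Optional per-class score matrix for
#'   [one_vs_rest_roc()].
#' @return Object of class `classification_report`; see [tidy()] /
#'   [glance()] methods for tabular access.
#' @export
classification_report <- function(true, predicted, vote_fractions = NULL) {
  true <- as.factor(true)
  predicted <- factor(predicted, levels = levels(true))
  if (length(true) != length(predicted)) {
    stop_slicecov("`true` and `predicted` have different lengths.",
                  "slicecov_length_mismatch")
  }
  classes <- levels(true)
  confusion <- table(true = true, predicted = predicted)
  accuracy <- 100 * sum(diag(confusion)) / length(true)
  per_class <- purrr::map(classes, function(cls) {
    pos <- true == cls
    tibble::tibble(
      class = cls, n = sum(pos),
      tpr = if (sum(pos) > 0) mean(predicted[pos] == cls) else NA_real_,
      tnr = if (sum(!pos) > 0) mean(predicted[!pos] != cls) else NA_real_)
  })
  per_class <- dplyr::bind_rows(per_class)
  roc <- if (!is.null(vote_fractions)) {
    one_vs_rest_roc(true, vote_fractions)
  }
  if (!is.null(roc)) {
    per_class <- dplyr::left_join(per_class, roc$aucs[, c("class", "auc")],
                                  by = "class")
  } else {
    per_class$auc <- NA_real_
  }
  structure(
    list(accuracy = accuracy, confusion = confusion, per_class = per_class,
         macro_tpr = mean(per_class$tpr, na.rm = TRUE),
         macro_tnr = mean(per_class$tnr, na.rm = TRUE),
         macro_auc = if (!is.null(roc)) roc$macro_auc else NA_real_,
         roc = roc, n = length(true)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> n = ", x$n,
      ", accuracy ", sprintf("%.1f%%", x$accuracy),
      ", macro TPR ", sprintf("%.3f", x$macro_tpr),
      ", macro TNR ", sprintf("%.3f", x$macro_tnr), sep = "")
  if (is.finite(x$macro_auc)) cat(", macro AUC ", sprintf("%.3f", x$macro_auc), sep = "")
  cat("\nConfusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Regression performance report
#'
#' Error metrics of predicted vs true percent coverage: MSE, RMSE and MAE
#' of the signed error `predicted - true`, Pearson and Spearman
#' correlations of the error with true coverage (does the model over- or
#' under-estimate systematically along the coverage range?), and a
#' Kolmogorov-Smirnov test of error normality against a normal law with
#' the sample mean and sd. Estimating those parameters from the same data
#' makes the KS p-value anti-conservative; it is reported as the customary
#' descriptive check, not a calibrated test.
#'
#' @param true,predicted Aligned numeric vectors, n >= 2.
#' @return Object of class `regression_report` with the per-case error
#'   tibble and summary statistics; see [tidy()] / [glance()].
#' @export
regression_report <- function(true, predicted) {
  true <- as.numeric(true); predicted <- as.numeric(predicted)
  if (length(true) != length(predicted)) {
    stop_slicecov("`true` and `predicted` have different lengths.",
                  "slicecov_length_mismatch")
  }
  if (length(true) < 2) {
    stop_slicecov("Need n >= 2 for a regression report.",
                  "slicecov_degenerate_eval")
  }
  error <- predicted - true
  mse <- mean(error^2)
  safe_cor <- function(a, b, method) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }
  ks_p <- if (stats::sd(error) > 0) {
    suppressWarnings(
      stats::ks.test(error, "pnorm", mean(error), stats::sd(error))$p.value)
  } else {
    NA_real_
  }
  structure(
    list(data = tibble::tibble(true = true, predicted = predicted, error = error),
         mse = mse, rmse = sqrt(mse), mae = mean(abs(error)),
         pearson_r = safe_cor(error, true, "pearson"),
         spearman_rho = safe_cor(error, true, "spearman"),
         ks_p = ks_p, n = length(true)),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report> n = ", x$n,
      ", MSE ", sprintf("%.1f", x$mse),
      ", RMSE ", sprintf("%.2f%%", x$rmse),
      ", MAE ", sprintf("%.2f%%", x$mae),
      ", r_p(error, true) ", sprintf("%.3f", x$pearson_r),
      ", KS p ", sprintf("%.3f", x$ks_p), "\n", sep = "")
  invisible(x)
}
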