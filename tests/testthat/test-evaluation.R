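make_votes <- function(scores_by_class) {
  m <- do.call(cbind, scores_by_class)
  colnames(m) <- coverage_class_levels()[seq_len(ncol(m))]
  m
}

test_that("perfectly ranked scores give AUC 1 and chance scores give 0.5", {
  lv <- coverage_class_levels()
  true <- factor(rep(lv, each = 5), levels = lv)
  votes <- matrix(0.05, 20, 4, dimnames = list(NULL, lv))
  votes[cbind(seq_len(20), as.integer(true))] <- 0.85
  roc <- one_vs_rest_roc(true, votes)
  expect_equal(roc$aucs$auc, rep(1, 4))
  expect_equal(roc$macro_auc, 1)

  # label-independent scores, large n
  withr::with_seed(1, {
    true2 <- factor(sample(lv, 2000, replace = TRUE), levels = lv)
    votes2 <- matrix(runif(2000 * 4), 2000, 4, dimnames = list(NULL, lv))
  })
  roc2 <- one_vs_rest_roc(true2, votes2)
  expect_true(all(abs(roc2$aucs$auc - 0.5) < 0.05))
})

test_that("trapezoidal AUC equals brute-force pair counting, ties included", {
  lv <- coverage_class_levels()
  for (rep_i in 1:10) {
    withr::with_seed(100 + rep_i, {
      n <- sample(10:50, 1)
      true <- factor(sample(lv, n, replace = TRUE), levels = lv)
      # coarse scores force ties
      votes <- matrix(round(runif(n * 4), 1), n, 4, dimnames = list(NULL, lv))
    })
    evaluable <- lv[table(true) > 0 & table(true) < n]
    if (length(evaluable) == 0) next
    roc <- suppressWarnings(one_vs_rest_roc(true, votes))
    for (cls in roc$aucs$class) {
      expect_equal(roc$aucs$auc[roc$aucs$class == cls],
                   auc_pair_count(true == cls, votes[, cls]),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  lv <- coverage_class_levels()
  withr::with_seed(3, {
    true <- factor(sample(lv, 40, replace = TRUE), levels = lv)
    votes <- matrix(runif(160), 40, 4, dimnames = list(NULL, lv))
  })
  a <- suppressWarnings(one_vs_rest_roc(true, votes))
  b <- suppressWarnings(one_vs_rest_roc(true, exp(3 * votes)))
  expect_equal(a$aucs$auc, b$aucs$auc, tolerance = 1e-12)
})

test_that("classes without positives or negatives are skipped with a warning", {
  lv <- coverage_class_levels()
  true <- factor(c(rep(lv[1], 5), rep(lv[2], 5)), levels = lv)
  votes <- matrix(runif(40), 10, 4, dimnames = list(NULL, lv))
  msgs <- capture_warnings(roc <- one_vs_rest_roc(true, votes))
  expect_true(all(grepl("skipped", msgs)))
  expect_length(msgs, 2)
  expect_setequal(roc$aucs$class, lv[1:2])

  one_class <- factor(rep(lv[1], 6), levels = lv)
  expect_error(suppressWarnings(one_vs_rest_roc(one_class, votes[1:6, ])),
               class = "slicecov_degenerate_eval")
})

test_that("classification report counts accuracy, TPR and TNR correctly", {
  lv <- coverage_class_levels()
  true <- factor(lv[c(1, 1, 2, 2, 3, 3, 4, 4)], levels = lv)
  rep_all <- classification_report(true, true)
  expect_equal(rep_all$accuracy, 100)
  expect_equal(rep_all$macro_tpr, 1)
  expect_equal(rep_all$macro_tnr, 1)
  expect_equal(sum(rep_all$confusion), 8)
  expect_equal(sum(diag(rep_all$confusion)), 8)

  # one case: true class 1 predicted as class 2
  single <- classification_report(factor(lv[1], levels = lv),
                                  factor(lv[2], levels = lv))
  expect_equal(single$confusion[lv[1], lv[2]], 1)
  expect_equal(single$accuracy, 0)

  mixed <- classification_report(
    factor(lv[c(1, 1, 2, 3)], levels = lv),
    factor(lv[c(1, 2, 2, 1)], levels = lv))
  expect_equal(mixed$accuracy, 100 * sum(diag(mixed$confusion)) / sum(mixed$confusion))
  expect_error(classification_report(true, true[1:3]),
               class = "slicecov_length_mismatch")
})

test_that("regression report reproduces hand-computed error metrics", {
  r0 <- regression_report(c(50, 60), c(50, 60))
  expect_equal(c(r0$mse, r0$rmse, r0$mae), c(0, 0, 0))

  r1 <- regression_report(c(50, 50), c(60, 40)) # errors +10, -10
  expect_equal(r1$mae, 10)
  expect_equal(r1$rmse, 10)
  expect_equal(r1$mse, 100)

  r2 <- regression_report(c(10, 20, 30, 40), c(13, 17, 33, 37)) # +/-3
  expect_equal(r2$mae, 3)
  expect_equal(r2$rmse, 3)

  expect_error(regression_report(50, 60), class = "slicecov_degenerate_eval")
  expect_error(regression_report(c(1, 2), 1),
               class = "slicecov_length_mismatch")
})

test_that("regression metrics are invariant under joint permutation and RMSE >= MAE", {
  withr::with_seed(5, {
    true <- runif(40, 20, 100)
    pred <- true + rnorm(40, sd = 8)
    perm <- sample(40)
  })
  a <- regression_report(true, pred)
  b <- regression_report(true[perm], pred[perm])
  expect_equal(glance(a)[c("mse", "rmse", "mae", "pearson_r", "ks_p")],
               glance(b)[c("mse", "rmse", "mae", "pearson_r", "ks_p")])
  expect_gte(a$rmse, a$mae)
  expect_true(a$ks_p >= 0 && a$ks_p <= 1)
})

test_that("tidiers expose report internals as tibbles", {
  lv <- coverage_class_levels()
  withr::with_seed(6, {
    true <- factor(sample(lv, 30, replace = TRUE), levels = lv)
    votes <- matrix(runif(120), 30, 4, dimnames = list(NULL, lv))
    votes <- votes / rowSums(votes)
  })
  pred <- factor(lv[max.col(votes)], levels = lv)
  cr <- suppressWarnings(classification_report(true, pred, votes))
  expect_s3_class(tidy(cr), "tbl_df")
  expect_equal(nrow(tidy(cr)), 4)
  expect_named(glance(cr), c("n", "accuracy", "macro_auc", "macro_tpr",
                             "macro_tnr"))
  rr <- regression_report(runif(10, 0, 100), runif(10, 0, 100))
  expect_equal(nrow(tidy(rr)), 10)
  expect_equal(glance(rr)$rmse, sqrt(glance(rr)$mse))
})
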