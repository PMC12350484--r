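test_that("coverage classes follow the documented bin boundaries", {
  lv <- coverage_class_levels()
  expect_equal(as.character(class_of(65)), "50-70")
  expect_equal(as.character(class_of(99)), ">=90")
  expect_equal(as.character(class_of(c(0, 50, 50.0001, 69.999, 70, 89.999, 90, 100))),
               c("<=50", "<=50", "50-70", "50-70", "70-90", "70-90",
                 ">=90", ">=90"))
  # total and monotone over the whole range
  grid <- seq(0, 100, by = 0.25)
  codes <- as.integer(class_of(grid))
  expect_false(anyNA(codes))
  expect_true(all(diff(codes) >= 0))
  expect_error(class_of(101), class = "slicecov_domain_error")
  expect_error(class_of(-1), class = "slicecov_domain_error")
})

# Synthetic difference vectors whose first coordinate encodes the signal.
signal_features <- function(n, seed, noise = 0.05) {
  withr::with_seed(seed, {
    cov <- runif(n, 0, 100)
    x <- cbind(cov + rnorm(n, sd = noise),
               matrix(rnorm(n * 19), n, 19))
    colnames(x) <- paste0("d", 1:20)
    list(x = x, coverage = cov)
  })
}

test_that("the class forest separates a trivially separable training set", {
  f <- signal_features(120, seed = 1)
  model <- train_classifier(f$x, class_of(f$coverage), seed = 1)
  pred <- predict_class(model, f$x)
  expect_equal(mean(pred$class_pred == class_of(f$coverage)), 1)

  votes <- as.matrix(pred[, paste0("vote_", coverage_class_levels())])
  expect_true(all(votes >= 0))
  expect_equal(rowSums(votes), rep(1, nrow(votes)), tolerance = 1e-12)
  # argmax decision with first-max (lower-class) tie handling
  expect_equal(as.integer(pred$class_pred),
               max.col(votes, ties.method = "first"))
})

test_that("classifier fits are reproducible per seed and reject one class", {
  f <- signal_features(60, seed = 2)
  m1 <- train_classifier(f$x, class_of(f$coverage), seed = 5)
  m2 <- train_classifier(f$x, class_of(f$coverage), seed = 5)
  p1 <- predict_class(m1, f$x); p2 <- predict_class(m2, f$x)
  expect_identical(p1, p2)

  expect_error(train_classifier(f$x, rep(class_of(95), 60), seed = 1),
               class = "slicecov_degenerate_training")
  expect_error(predict_class(m1, f$x[, 1:10]),
               class = "slicecov_dim_mismatch")
})

# Coverages drawn so the four classes are balanced (chance accuracy 1/4).
balanced_features <- function(n, seed, noise = 0.05) {
  withr::with_seed(seed, {
    lo <- c(0, 50.5, 70, 90); hi <- c(50, 69.5, 89.5, 100)
    cls <- sample(1:4, n, replace = TRUE)
    cov <- runif(n, lo[cls], hi[cls])
    x <- cbind(cov + rnorm(n, sd = noise), matrix(rnorm(n * 19), n, 19))
    colnames(x) <- paste0("d", 1:20)
    list(x = x, coverage = cov)
  })
}

test_that("permuting labels drops test accuracy to chance", {
  f_train <- balanced_features(200, seed = 3)
  f_test <- balanced_features(200, seed = 4)
  y_perm <- withr::with_seed(9, sample(class_of(f_train$coverage)))
  model <- train_classifier(f_train$x, y_perm, seed = 1)
  acc <- mean(predict_class(model, f_test$x)$class_pred ==
                class_of(f_test$coverage))
  expect_lt(abs(acc - 0.25), 0.12)
})

test_that("the forest regressor learns a linear signal and is seed-stable", {
  f_train <- signal_features(150, seed = 5)
  f_test <- signal_features(60, seed = 6)
  model <- train_regressor(f_train$x, f_train$coverage, variant = "rf", seed = 1)
  pred <- predict_coverage(model, f_test$x)
  mae <- mean(abs(pred - f_test$coverage))
  baseline <- mean(abs(mean(f_train$coverage) - f_test$coverage))
  expect_lt(mae, baseline / 2)
  expect_true(all(pred <= 100))

  m2 <- train_regressor(f_train$x, f_train$coverage, variant = "rf", seed = 1)
  expect_identical(pred, predict_coverage(m2, f_test$x))
})

test_that("regression predictions are clamped at 100 but not below", {
  withr::with_seed(1, {
    x <- matrix(rnorm(80 * 5), 80, 5); colnames(x) <- paste0("d", 1:5)
  })
  high <- train_regressor(x, rep(110, 80) + x[, 1], variant = "rf", seed = 1)
  expect_true(all(predict_coverage(high, x) == 100))

  const <- train_regressor(x, rep(76, 80), variant = "rf", seed = 1)
  expect_equal(predict_coverage(const, x), rep(76, 80), tolerance = 1e-9)
})

test_that("the DNN head trains for exactly 30 epochs and learns the signal", {
  f_train <- signal_features(120, seed = 7)
  f_test <- signal_features(50, seed = 8)
  model <- train_regressor(f_train$x, f_train$coverage, variant = "dnn",
                           seed = 2, hidden = c(64, 16))
  expect_length(model$loss_history, 30)
  expect_lt(tail(model$loss_history, 1), model$loss_history[1])
  expect_true(is.logical(model$converged))
  pred <- predict_coverage(model, f_test$x)
  expect_true(all(is.finite(pred)) && all(pred <= 100))
  mae <- mean(abs(pred - f_test$coverage))
  baseline <- mean(abs(mean(f_train$coverage) - f_test$coverage))
  expect_lt(mae, baseline)

  m2 <- train_regressor(f_train$x, f_train$coverage, variant = "dnn",
                        seed = 2, hidden = c(64, 16))
  expect_identical(predict_coverage(model, f_test$x),
                   predict_coverage(m2, f_test$x))
})

test_that("both regressor variants reproduce constant labels", {
  withr::with_seed(3, {
    x <- matrix(rnorm(60 * 8), 60, 8); colnames(x) <- paste0("d", 1:8)
  })
  for (v in c("rf", "dnn")) {
    m <- train_regressor(x, rep(64, 60), variant = v, seed = 1,
                         hidden = c(32, 8))
    expect_equal(predict_coverage(m, x), rep(64, 60), tolerance = 0.5)
  }
  expect_error(train_regressor(x[1, , drop = FALSE], 50),
               class = "slicecov_degenerate_training")
})
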