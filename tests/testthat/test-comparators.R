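test_that("Sturges' formula gives the cross-validation fold count", {
  expect_equal(sturgesFolds(9600), 14L)  # 8 animals x 1200 frames
  expect_equal(sturgesFolds(2), 2L)
  expect_equal(sturgesFolds(1024), 11L)
  expect_error(sturgesFolds(1), "n >= 2")
})

test_that("classifier specs validate their hyperparameters", {
  expect_s3_class(classifierSpec("rf"), "classifierSpec")
  expect_equal(classifierSpec("rf")$mtry, 1L)
  expect_equal(classifierSpec("rf")$ntree, 500L)
  expect_equal(classifierSpec("nn")$size, 10L)
  expect_error(classifierSpec("rf", mtry = 0), "positive")
  expect_error(classifierSpec("svm", cost_grid = c(1, -1)), "positive")
})

test_that("all three methods separate well-separated classes nearly perfectly", {
  set.seed(3)
  n <- 250L
  X <- rbind(matrix(rnorm(3 * n, 0, 0.2), ncol = 3L),
             matrix(rnorm(3 * n, 3, 0.2), ncol = 3L))
  y <- rep(c(0L, 2L), each = n)
  for (m in c("rf", "svm", "nn")) {
    spec <- classifierSpec(m, seed = 9, sigma_grid = 1, cost_grid = 1)
    fit <- trainFrameClassifier(spec, X, y)
    expect_gte(mean(predictFrames(fit, X) == y), 0.99)
  }
})

test_that("single-class training sets and dimension mismatches error", {
  X <- matrix(rnorm(30), 10L, 3L)
  expect_error(trainFrameClassifier(classifierSpec("rf"), X, rep(0L, 10L)),
               "single-class")
  fit <- trainFrameClassifier(classifierSpec("rf"), X, rep(c(0L, 1L), 5L))
  expect_error(predictFrames(fit, matrix(0, 2L, 2L)), "dimension mismatch")
  expect_warning(
    trainFrameClassifier(classifierSpec("rf"),
                         cbind(X[, 1:2], 1), rep(c(0L, 1L), 5L)),
    "constant feature")
})

test_that("predictions are frame-independent and empty input yields empty output", {
  set.seed(4)
  X <- rbind(matrix(rnorm(90, 0, 0.3), ncol = 3L),
             matrix(rnorm(90, 4, 0.3), ncol = 3L))
  y <- rep(c(0L, 1L), each = 30L)
  fit <- trainFrameClassifier(classifierSpec("rf", seed = 2), X, y)
  Z <- matrix(rnorm(60, 2, 2), 20L, 3L)
  p <- predictFrames(fit, Z)
  perm <- sample(nrow(Z))
  expect_equal(predictFrames(fit, Z[perm, ]), p[perm])
  expect_length(predictFrames(fit, Z[0L, , drop = FALSE]), 0L)
})

test_that("identical spec, seed and data give identical fits and predictions", {
  set.seed(5)
  X <- rbind(matrix(rnorm(150, 0, 1), ncol = 3L),
             matrix(rnorm(150, 2, 1), ncol = 3L))
  y <- rep(c(0L, 2L), each = 50L)
  Z <- matrix(rnorm(90), 30L, 3L)
  for (m in c("rf", "svm", "nn")) {
    spec <- classifierSpec(m, seed = 42, sigma_grid = c(0.5, 2),
                           cost_grid = 1, folds = 3)
    p1 <- predictFrames(trainFrameClassifier(spec, X, y), Z)
    p2 <- predictFrames(trainFrameClassifier(spec, X, y), Z)
    expect_identical(p1, p2)
  }
})

test_that("the SVM grid search records the selected kernel width and cost", {
  set.seed(6)
  X <- rbind(matrix(rnorm(120, 0, 0.4), ncol = 3L),
             matrix(rnorm(120, 3, 0.4), ncol = 3L))
  y <- rep(c(0L, 2L), each = 40L)
  spec <- classifierSpec("svm", seed = 7, sigma_grid = c(0.01, 1),
                         cost_grid = c(0.1, 1), folds = 3)
  fit <- trainFrameClassifier(spec, X, y)
  expect_true(fit$tuning$sigma %in% spec$sigma_grid)
  expect_true(fit$tuning$cost %in% spec$cost_grid)
  expect_equal(fit$tuning$folds, 3L)
  expect_equal(nrow(fit$tuning$grid), 4L)
})

test_that("a random forest with the study hyperparameters learns a synthetic cohort", {
  co <- simulateCohort(recoveryConfig(seed = 31, K = 400L))
  train_ids <- firstTrainingIds(co)
  test_ids <- setdiff(names(co$trajectories), train_ids)
  tm <- stackTrainingMatrix(co$trajectories[train_ids])
  fit <- trainFrameClassifier(classifierSpec("rf", seed = 1),
                              tm[, c("x", "y", "L")], tm[, "label"])
  acc <- mean(unlist(lapply(co$trajectories[test_ids], function(tr)
    predictFrames(fit, makeObservations(tr)) == attr(tr, "true_states"))))
  expect_gte(acc, 0.95)
})
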