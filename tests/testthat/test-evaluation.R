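test_that("the tolerance window matches behavior frames one frame apart", {
  K <- 20L
  obs <- integer(K); obs[10L] <- 1L
  pred <- integer(K); pred[11L] <- 1L
  expect_equal(windowedConcordanceCounts(pred, obs, 1L, window = 1L),
               c(TP = 1L, FN = 0L, FP = 0L))
  pred2 <- integer(K); pred2[12L] <- 1L  # outside the +/-1 window
  expect_equal(windowedConcordanceCounts(pred2, obs, 1L, window = 1L),
               c(TP = 0L, FN = 1L, FP = 1L))
  # identical sequences: all observed-behavior frames are TPs
  set.seed(1)
  lab <- sample(0:2, 100L, replace = TRUE)
  expect_equal(windowedConcordanceCounts(lab, lab, 2L, window = 1L),
               c(TP = sum(lab == 2L), FN = 0L, FP = 0L))
  expect_error(windowedConcordanceCounts(1:3, 1:4, 1L), "equal length")
})

test_that("window 0 reduces to exact frame agreement and windows are monotone", {
  set.seed(2)
  obs <- sample(0:2, 300L, replace = TRUE)
  pred <- obs
  flip <- sample(300L, 60L)
  pred[flip] <- (pred[flip] + 1L) %% 3L
  for (b in c(1L, 2L)) {
    c0 <- windowedConcordanceCounts(pred, obs, b, window = 0L)
    expect_equal(c0[["TP"]], sum(obs == b & pred == b))
    expect_equal(c0[["FN"]], sum(obs == b & pred != b))
    expect_equal(c0[["FP"]], sum(pred == b & obs != b))
    prev <- c0
    for (w in 1:4) {
      cw <- windowedConcordanceCounts(pred, obs, b, window = w)
      expect_gte(cw[["TP"]], prev[["TP"]])
      expect_lte(cw[["FN"]], prev[["FN"]])
      expect_lte(cw[["FP"]], prev[["FP"]])
      prev <- cw
    }
  }
})

test_that("PC follows the study conventions including the all-absent case", {
  expect_equal(percentageConcordance(50, 25, 25)[["PC"]], 50)
  # behavior absent in both sequences: full agreement
  expect_equal(percentageConcordance(0, 0, 0),
               c(PC = 100, FP_pct = 0, FN_pct = 0))
  # behavior only ever predicted: PC 0 with FP share 100
  pc <- percentageConcordance(0, 0, 7)
  expect_equal(pc[["PC"]], 0)
  expect_equal(pc[["FP_pct"]], 100)
  expect_error(percentageConcordance(-1, 0, 0), "non-negative")
  # the three shares always sum to 100 when any count is positive
  set.seed(3)
  for (i in 1:20) {
    cts <- rpois(3, 5)
    if (sum(cts) == 0) cts[1] <- 1
    expect_equal(sum(percentageConcordance(cts[1], cts[2], cts[3])), 100)
  }
})

test_that("PC is invariant to relabeling of non-target states", {
  set.seed(4)
  obs <- sample(0:2, 200L, replace = TRUE)
  pred <- sample(0:2, 200L, replace = TRUE)
  # swap states 0 and 1 everywhere; scoring behavior 2 must not change
  swap <- function(v) ifelse(v == 0L, 1L, ifelse(v == 1L, 0L, v))
  expect_equal(windowedConcordanceCounts(pred, obs, 2L),
               windowedConcordanceCounts(swap(pred), swap(obs), 2L))
})

test_that("time budgets count state shares and approach stationarity", {
  lab <- c(rep(2L, 600L), rep(0L, 600L))
  expect_equal(behaviorTimeBudget(lab),
               c(approaching = 0, standing = 50))
  expect_equal(behaviorTimeBudget(rep(0L, 10L)),
               c(approaching = 0, standing = 0))
  truth <- defaultEstrusTransition()
  tr <- simulateTrajectory(stateProfile(), truth, K = 1e5L, seed = 13,
                           mode = "gaussian")
  bud <- behaviorTimeBudget(trajLabels(tr))
  stat <- 100 * stationaryDistribution(truth)
  expect_lt(abs(bud[["approaching"]] - stat[2L]), 2)
  expect_lt(abs(bud[["standing"]] - stat[3L]), 2)
})

test_that("budget t-tests flag degenerate pairs and detect a constant shift", {
  same <- c(10, 20, 30, 40)
  expect_true(compareBudgetsTTest(same, same)$degenerate)
  expect_true(compareBudgetsTTest(5, 5)$degenerate)  # n < 2
  set.seed(5)
  base <- rnorm(8, 50, 3)
  res <- compareBudgetsTTest(base + rnorm(8, 5, 1), base)  # shift 5, sd 1
  expect_false(res$degenerate)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$mean_difference, 5, tolerance = 0.5)
  expect_equal(res$df, 7)
})

test_that("paired t-test type-I error is calibrated at the nominal level", {
  set.seed(17)
  rejections <- vapply(1:1000, function(i) {
    base <- rnorm(8, 50, 5)
    res <- compareBudgetsTTest(base + rnorm(8), base)  # null: same budgets
    res$p_value < 0.05
  }, logical(1L))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("concordance tables cover every animal and behavior", {
  set.seed(6)
  obs <- list(a = sample(0:2, 50L, TRUE), b = sample(0:2, 50L, TRUE))
  pred <- list(a = obs$a, b = sample(0:2, 50L, TRUE))
  tab <- concordanceTable(pred, obs, training_ids = "a")
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$behavior, c("approaching", "standing"))
  expect_true(all(tab$PC[tab$animal_id == "a"] == 100))
  expect_equal(tab$is_training, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(concordanceTable(pred["a"], obs), "same animals")
})
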