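test_that("transition counting matches hand counts and handles unseen states", {
  tm <- estimateTransitionMatrix(list(c(0, 0, 1, 1, 2, 2, 0)))
  expected <- rbind(c(1/2, 1/2, 0), c(0, 1/2, 1/2), c(1/2, 0, 1/2))
  expect_equal(unname(tm$T), expected, tolerance = 1e-9)
  expect_equal(unname(tm$pi), c(1, 0, 0), tolerance = 1e-9)

  const <- estimateTransitionMatrix(list(c(1, 1, 1, 1)))
  expect_equal(unname(const$T[2L, ]), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(unname(const$T[1L, ]), rep(1/3, 3))  # unseen-state rule
  expect_equal(unname(const$T[3L, ]), rep(1/3, 3))
  expect_true(all(const$T > 0))  # flooring keeps log-probabilities finite

  expect_error(estimateTransitionMatrix(list()), "no label sequences")
  expect_error(estimateTransitionMatrix(list(c(0, 3))), "labels must lie")
})

test_that("a long simulated chain recovers its generating transition matrix", {
  truth <- defaultEstrusTransition()
  tr <- simulateTrajectory(stateProfile(), truth, K = 1e5L, seed = 17,
                           mode = "gaussian")
  est <- estimateTransitionMatrix(list(trajLabels(tr)))
  expect_lt(max(abs(est$T - truth$T)), 0.02)
})

test_that("filtering with state-blind emissions reproduces the chain marginals", {
  set.seed(31)
  em <- fitStateGMM(matrix(rnorm(60), 20L, 3L), m = 1L)
  T_mat <- rbind(c(0.8, 0.15, 0.05), c(0.2, 0.6, 0.2), c(0.1, 0.3, 0.6))
  pi <- c(0.5, 0.3, 0.2)
  model <- structure(list(transition = transitionModel(T_mat, pi),
                          emissions = list(em, em, em)),
                     class = "estrusHMM")
  K <- 10L
  Z <- matrix(rnorm(3 * K), K, 3L)
  fw <- forwardFilter(model, Z)
  sm <- backwardSmooth(model, fw)
  marg <- pi
  for (k in seq_len(K)) {
    expect_equal(unname(fw$filtered[k, ]), marg, tolerance = 1e-12)
    expect_equal(unname(sm[k, ]), marg, tolerance = 1e-12)
    marg <- as.numeric(marg %*% T_mat)
  }
})

test_that("forward-backward equals brute-force path enumeration", {
  worst <- 0
  for (i in 1:50) {
    model <- randomModel(seed = 100 + i, m = if (i %% 2) 1L else 2L)
    K <- 2L + (i %% 7L)  # K in 2..8
    set.seed(1000 + i)
    Z <- matrix(rnorm(3 * K, sd = 2), K, 3L)
    fw <- forwardFilter(model, Z)
    sm <- backwardSmooth(model, fw)
    bf <- bruteForcePosterior(model, Z)
    worst <- max(worst, max(abs(sm - bf)))
  }
  expect_lt(worst, 1e-8)
})

test_that("smoothing degenerates correctly at K = 1 and the oracle guards its size", {
  model <- randomModel(1)
  Z <- matrix(rnorm(3), 1L, 3L)
  fw <- forwardFilter(model, Z)
  expect_equal(backwardSmooth(model, fw), fw$filtered)
  # K = 1 posterior is Bayes' rule: pi_s * p(z|s), normalized
  lp <- emissionLogDensity(model, Z)[1L, ] + log(model$transition$pi)
  expect_equal(unname(bruteForcePosterior(model, Z)[1L, ]),
               unname(exp(lp) / sum(exp(lp))), tolerance = 1e-12)
  expect_error(bruteForcePosterior(model, matrix(rnorm(36), 12L, 3L)),
               "K > 10")
})

test_that("MAP decoding takes the per-frame argmax with ties to the smallest state", {
  onehot <- diag(3)[c(2, 1, 3), ]
  expect_equal(decodeMAP(onehot), c(1L, 0L, 2L))
  expect_equal(decodeMAP(matrix(1/3, 1L, 3L)), 0L)
  expect_equal(decodeMAP(rbind(c(0.2, 0.4, 0.4))), 1L)
  # agrees with the exact marginal argmax on small random instances
  for (i in 1:10) {
    model <- randomModel(200 + i)
    set.seed(300 + i)
    Z <- matrix(rnorm(18), 6L, 3L)
    sm <- backwardSmooth(model, forwardFilter(model, Z))
    expect_equal(decodeMAP(sm), decodeMAP(bruteForcePosterior(model, Z)))
  }
})

test_that("posterior rows are probability vectors even with extreme densities", {
  model <- randomModel(5)
  for (s in 1:3) model$emissions[[s]]$variances[] <- 1e-6  # huge densities
  set.seed(6)
  Z <- matrix(rnorm(1500, sd = 3), 500L, 3L)
  fw <- forwardFilter(model, Z)
  sm <- backwardSmooth(model, fw)
  expect_true(all(is.finite(sm)))
  expect_lt(max(abs(rowSums(sm) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fw$filtered) - 1)), 1e-9)
  expect_true(is.finite(fw$loglik))
})

test_that("smoothed posteriors are invariant to a common affine change of units", {
  # rescaling z -> a z + b scales every state's density by 1/a^3 at every
  # frame; the posteriors must not move (log-space normalization check)
  model <- randomModel(8, m = 2L)
  set.seed(9)
  Z <- matrix(rnorm(60), 20L, 3L)
  a <- 1000; b <- -50
  scaled <- model
  for (s in 1:3) {
    scaled$emissions[[s]]$means <- a * model$emissions[[s]]$means + b
    scaled$emissions[[s]]$variances <- a^2 * model$emissions[[s]]$variances
  }
  sm <- backwardSmooth(model, forwardFilter(model, Z))
  sm2 <- backwardSmooth(scaled, forwardFilter(scaled, a * Z + b))
  expect_equal(sm, sm2, tolerance = 1e-9)
})

test_that("models serialize to JSON and round-trip bit-exactly", {
  model <- randomModel(12, m = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  writeHMMModel(model, path)
  back <- readHMMModel(path)
  expect_identical(unname(back$transition$T), unname(model$transition$T))
  expect_identical(back$transition$pi, model$transition$pi)
  for (s in 1:3) {
    expect_identical(back$emissions[[s]]$weights,
                     model$emissions[[s]]$weights)
    expect_identical(unname(back$emissions[[s]]$means),
                     unname(model$emissions[[s]]$means))
    expect_identical(unname(back$emissions[[s]]$variances),
                     unname(model$emissions[[s]]$variances))
  }
  set.seed(99)
  Z <- matrix(rnorm(30), 10L, 3L)
  expect_identical(decodeStates(back, Z)$smoothed,
                   decodeStates(model, Z)$smoothed)
})
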