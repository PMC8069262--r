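test_that("forward pass reproduces hand-worked values", {
  # zero net: sigma(0) = 0.5 whatever the input
  m0 <- mlpModel(c(3, 1), dropoutRate = 0, seed = 1L)
  m0@weights[[1]][] <- 0; m0@biases[[1]][] <- 0
  expect_equal(mlpForward(m0, c(5, -2, 100)), 0.5)
  # ReLU clamps negatives, passes positives
  expect_equal(nirmsi:::actFn(c(-3, 2), "relu"), c(0, 2))
  # 2-2-1 chain, worked by hand:
  #   z1 = (1*0.5 + 2*1.0 + 0.1, 1*(-0.25) + 2*0.75 - 0.2) = (2.6, 1.05)
  #   relu passthrough; z2 = 2.6*0.3 - 1.05*0.4 + 0.05 = 0.41
  m <- mlpModel(c(2, 2, 1), dropoutRate = 0, seed = 1L)
  m@weights[[1]] <- matrix(c(0.5, 1.0, -0.25, 0.75), 2, 2)
  m@biases[[1]] <- c(0.1, -0.2)
  m@weights[[2]] <- matrix(c(0.3, -0.4), 2, 1)
  m@biases[[2]] <- 0.05
  expect_equal(mlpForward(m, c(1, 2)), 1 / (1 + exp(-0.41)), tolerance = 1e-12)
  expect_error(mlpForward(m, c(1, 2, 3)), "expects")
})

test_that("backpropagation matches central finite differences", {
  set.seed(40)
  m <- mlpModel(c(3, 4, 1), dropoutRate = 0, seed = 2L)
  X <- matrix(rnorm(24), 8, 3); y <- rep(c(0, 1), 4)
  g <- nirmsi:::mlpGradients(m, X, y)
  h <- 1e-5
  relErr <- 0
  for (l in 1:2) {
    for (i in seq_along(m@weights[[l]])) {
      mp <- m; mp@weights[[l]][i] <- m@weights[[l]][i] + h
      mm <- m; mm@weights[[l]][i] <- m@weights[[l]][i] - h
      fd <- (nirmsi:::mlpGradients(mp, X, y)$loss -
             nirmsi:::mlpGradients(mm, X, y)$loss) / (2 * h)
      relErr <- max(relErr, abs(fd - g$dW[[l]][i]) / max(abs(fd), 1e-8))
    }
    for (i in seq_along(m@biases[[l]])) {
      mp <- m; mp@biases[[l]][i] <- m@biases[[l]][i] + h
      mm <- m; mm@biases[[l]][i] <- m@biases[[l]][i] - h
      fd <- (nirmsi:::mlpGradients(mp, X, y)$loss -
             nirmsi:::mlpGradients(mm, X, y)$loss) / (2 * h)
      relErr <- max(relErr, abs(fd - g$db[[l]][i]) / max(abs(fd), 1e-8))
    }
  }
  expect_lt(relErr, 1e-5)
})

test_that("output bias gradient vanishes for a zero net on a balanced batch", {
  m <- mlpModel(c(2, 2, 1), dropoutRate = 0, seed = 3L)
  for (l in 1:2) { m@weights[[l]][] <- 0; m@biases[[l]][] <- 0 }
  g <- nirmsi:::mlpGradients(m, matrix(rnorm(8), 4, 2), c(0, 1, 0, 1))
  # sigma(0) = 0.5 cancels against the 50/50 target mix
  expect_equal(g$db[[2]], 0, tolerance = 1e-14)
})

test_that("a dropout mask zeroing a unit kills all gradients through it", {
  set.seed(41)
  m <- mlpModel(c(3, 4, 1), dropoutRate = 0.5, seed = 4L)
  X <- matrix(rnorm(15), 5, 3); y <- c(0, 1, 1, 0, 1)
  masks <- list(matrix(1, 5, 3), matrix(1, 5, 4))
  masks[[2]][, 2] <- 0                       # hidden unit 2 dropped everywhere
  g <- nirmsi:::mlpGradients(m, X, y, trainMode = TRUE, masks = masks)
  expect_equal(g$dW[[2]][2, 1], 0)
  expect_equal(max(abs(g$dW[[1]][, 2])), 0)
  expect_equal(g$db[[1]][2], 0)
})

test_that("eval forward equals the exact dropout-mask expectation of a linear net", {
  m <- mlpModel(c(2, 2, 1), hiddenActivation = "identity", dropoutRate = 0.4,
                seed = 5L)
  x <- matrix(c(0.7, -1.3), 1, 2)
  p <- m@dropoutRate
  combos <- expand.grid(rep(list(0:1), 4))
  expectLogit <- 0
  for (r in seq_len(nrow(combos))) {
    bits <- as.numeric(combos[r, ])
    masks <- list(matrix(bits[1:2], 1, 2), matrix(bits[3:4], 1, 2))
    w <- prod(ifelse(bits == 1, 1 - p, p))
    out <- nirmsi:::mlpForwardFull(m, x, trainMode = TRUE, masks = masks,
                                   rawLogit = TRUE)$out
    expectLogit <- expectLogit + w * out
  }
  evalLogit <- nirmsi:::mlpForwardFull(m, x, rawLogit = TRUE)$out
  expect_equal(expectLogit, evalLogit, tolerance = 1e-12)
})

test_that("training is deterministic and solves a well-separated toy problem", {
  set.seed(42)
  X <- rbind(matrix(rnorm(300), 150, 2), matrix(rnorm(300, mean = 6), 150, 2))
  y <- rep(0:1, each = 150)
  cfg <- trainConfig(epochs = 50L, batchSize = 64L, learningRate = 1e-2,
                     dropoutRate = 0, seed = 6L)
  fit <- trainMLP(list(X = X, y = y), layerSizes = c(8L), config = cfg)
  acc <- mean((mlpForward(fit$model, X) >= 0.5) == y)
  expect_gte(acc, 0.99)
  fit2 <- trainMLP(list(X = X, y = y), layerSizes = c(8L), config = cfg)
  expect_identical(fit$model@weights, fit2$model@weights)
  expect_identical(fit$lossHistory, fit2$lossHistory)
  # loss eventually non-increasing over 5-epoch windows
  win <- vapply(seq(1, 46, by = 5), function(s) mean(fit$lossHistory[s:(s + 4)]), 0)
  expect_true(all(diff(win[3:length(win)]) <= 1e-3))
  expect_error(trainMLP(list(X = X, y = rep(0L, 300)), config = cfg), "both classes")
})

test_that("full-batch training is invariant to training-row order", {
  set.seed(43)
  X <- rbind(matrix(rnorm(120), 60, 2), matrix(rnorm(120, mean = 2), 60, 2))
  y <- rep(0:1, each = 60)
  cfg <- trainConfig(epochs = 30L, batchSize = 120L, learningRate = 1e-2,
                     dropoutRate = 0, seed = 7L)
  perm <- sample.int(120)
  f1 <- trainMLP(list(X = X, y = y), layerSizes = c(4L), config = cfg)
  f2 <- trainMLP(list(X = X[perm, ], y = y[perm]), layerSizes = c(4L), config = cfg)
  grid <- matrix(rnorm(40), 20, 2)
  expect_equal(mlpForward(f1$model, grid), mlpForward(f2$model, grid),
               tolerance = 1e-6)
})

test_that("probability maps respect validity, degeneracy and the 60% cutoff", {
  set.seed(44)
  H <- 6L; W <- 6L; B <- 4L
  v <- array(runif(H * W * B, 0.2, 1.2), c(H, W, B))
  valid <- matrix(TRUE, H, W); valid[1, 1] <- FALSE
  v[1, 1, ] <- NaN
  v[2, 2, ] <- 0.8                       # constant spectrum
  cube <- spectralCube(v, seq(1000, length.out = B, by = 100), valid = valid,
                       space = "absorbance")
  m <- mlpModel(c(B, 3, 1), dropoutRate = 0, seed = 8L)
  pm <- predictMap(m, cube)
  expect_true(is.na(cubeValues(pm)[1, 1]))
  expect_true(is.na(cubeValues(pm)[2, 2]))
  expect_true(attr(pm, "degenerate")[2, 2])
  expect_false(attr(pm, "degenerate")[1, 1])  # invalid, not degenerate
  expect_error(predictMap(mlpModel(c(B + 1, 3, 1), seed = 1L), cube), "band")

  # cutoff boundary: p >= 0.60 is tumor, 0.599 is not
  pv <- matrix(NaN, 2, 2); pv[1, 1] <- 0.60; pv[1, 2] <- 0.599; pv[2, 1] <- 0.9
  pmap <- new("ProbabilityMap", values = pv, cutoff = 0.60)
  bin <- binarize(pmap)
  expect_true(bin[1, 1]); expect_false(bin[1, 2]); expect_true(bin[2, 1])
  expect_false(bin[2, 2])
  expect_true(attr(bin, "unscored")[2, 2])
  allNaN <- new("ProbabilityMap", values = matrix(NaN, 2, 2), cutoff = 0.6)
  expect_equal(sum(binarize(allNaN)), 0)
})
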