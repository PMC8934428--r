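test_that("CNN architecture report reproduces every printed cell", {
  m <- buildCnn(4)
  r <- m$layerReport
  expect_equal(r$parameters,
               c(0, 1515, 60, 0, 0, 2490, 60, 0, 0, 760, 40, 0, 648, 36, 5))
  expect_equal(r$output,
               c("4x256x1", "1x232x15", "1x232x15", "1x58x15", "1x58x15",
                 "1x48x15", "1x48x15", "1x12x15", "1x12x15", "1x8x10",
                 "1x8x10", "1x8x10", "8", "4", "1"))
  expect_equal(sum(r$parameters), 5614)
  # stored parameter shapes agree with the report
  expect_equal(length(m$params$W1) + length(m$params$b1), 1515)
  expect_equal(length(m$params$Wd1) + length(m$params$bd1), 648)
  expect_error(buildCnn(4, inputLength = 20), "too short")
})

test_that("RNN architecture report matches the LSTM parameter formulas", {
  m <- buildRnn(4)
  expect_equal(m$layerReport$parameters, c(0, 2000, 0, 420, 0, 21))
  expect_equal(length(m$params$W) + length(m$params$b), 2000)
  expect_equal(length(m$params$V) + length(m$params$c0), 420)
  # oracle formula 4*((C+h)*h + h) at other widths
  for (C in c(1, 2, 7)) {
    mm <- buildRnn(C)
    expect_equal(mm$layerReport$parameters[2], 4 * ((C + 20) * 20 + 20))
    expect_equal(length(mm$params$W) + length(mm$params$b),
                 mm$layerReport$parameters[2])
  }
})

test_that("input normalization and lintanh follow their definitions", {
  expect_equal(normalizeInput(0, 3), 0)
  expect_equal(normalizeInput(5, 1), tanh(1))
  expect_equal(normalizeInput(5, 1, linear = TRUE), 1 / 1.2)
  x <- sort(rnorm(50))
  expect_true(all(diff(normalizeInput(x, 2)) >= 0))   # order preserved
  expect_true(all(abs(normalizeInput(rnorm(100, sd = 50), 10)) < 1))
  expect_error(normalizeInput(1, 0), "positive")

  expect_equal(lintanh(0), 0)
  expect_equal(lintanh(2), 1)
  expect_equal(lintanh(-3), -1)
  expect_equal(lintanh(0.6), 0.5)
  expect_equal(lintanh(c(1.2, -1.2)), c(1, -1))
  # uniform deviation bound from tanh, checked on a dense grid
  g <- seq(-6, 6, by = 1e-3)
  expect_lte(max(abs(lintanh(g) - tanh(g))), 0.17)
})

test_that("time derivative differences subsequent samples per channel", {
  expect_equal(as.numeric(timeDerivative(c(1, 2, 4, 8))), c(1, 2, 4))
  expect_true(all(timeDerivative(rep(5, 100)) == 0))
  ramp <- timeDerivative(seq(0, 99) * 0.25)
  expect_true(all(abs(ramp - 0.25) < 1e-12))
  # padding preserves length by repeating the first difference
  p <- timeDerivative(c(1, 2, 4, 8), pad = TRUE)
  expect_equal(as.numeric(p), c(1, 1, 2, 4))
  expect_error(timeDerivative(3), "at least 2")
})

test_that("window cutting respects role-specific strides and labels", {
  fs <- 256
  x <- matrix(rnorm(10 * fs * 4, sd = 10), ncol = 4)
  cfg <- trainConfig()
  # fully interictal 10 s signal, train role: stride 16
  rec <- eegRecording(x, fs, referenced = TRUE)
  tw <- makeTrainingWindows(rec, seizureAnnotations(data.frame(
    onset = numeric(), offset = numeric())), "train", cfg)
  expect_equal(dim(tw$windows)[1], floor((2560 - 256) / 16) + 1)  # 145
  expect_true(all(tw$labels == 0))

  # fully ictal signal, stride 1
  ann <- seizureAnnotations(0, 10)
  ti <- makeTrainingWindows(rec, ann, "train", cfg)
  expect_equal(dim(ti$windows)[1], 2560 - 256 + 1)  # 2305
  expect_true(all(ti$labels == 1))

  # test role: one window per second
  tt <- makeTrainingWindows(rec, ann, "test", cfg)
  expect_equal(dim(tt$windows)[1], 10)
  expect_equal(tt$starts, 0:9)
})

test_that("random forest honours its stated hyperparameters", {
  set.seed(5)
  n <- 400
  feats <- matrix(rnorm(n * 64), n, 64,
                  dimnames = list(NULL, paste0("f", 1:64)))
  labels <- as.integer(feats[, 1] + feats[, 2] > 0)
  m <- trainRf(feats, labels, rngSeed = 9)
  expect_equal(m$fit$num.trees, 100)
  expect_equal(m$fit$mtry, 4)
  depths <- vapply(1:100, function(i) {
    ti <- ranger::treeInfo(m$fit, i)
    # depth from the child-pointer structure
    depth <- integer(nrow(ti))
    for (r in seq_len(nrow(ti))) {
      if (!is.na(ti$leftChild[r])) {
        depth[ti$leftChild[r] + 1] <- depth[r] + 1
        depth[ti$rightChild[r] + 1] <- depth[r] + 1
      }
    }
    max(depth)
  }, numeric(1))
  expect_true(all(depths <= 10))

  # separable toy features: training-set accuracy 1
  sep <- matrix(c(rnorm(50, -4), rnorm(50, 4)), ncol = 1)
  sepf <- cbind(sep, matrix(rnorm(100 * 15), 100, 15))
  colnames(sepf) <- paste0("g", 1:16)
  ms <- trainRf(sepf, rep(0:1, each = 50), rngSeed = 2)
  pr <- predict(ms$fit, data = as.data.frame(sepf), num.threads = 1)$predictions
  expect_equal(as.integer(pr[, "1"] > 0.5), rep(0:1, each = 50))

  expect_error(trainRf(feats, rep(1, n)), "both classes")

  # determinism under a fixed seed
  m2 <- trainRf(feats, labels, rngSeed = 9)
  p1 <- predict(m$fit, data = as.data.frame(feats), num.threads = 1)$predictions
  p2 <- predict(m2$fit, data = as.data.frame(feats), num.threads = 1)$predictions
  expect_identical(p1, p2)
})

test_that("network training reduces loss on a separable toy problem", {
  set.seed(77)
  n <- 120
  X <- array(rnorm(n * 256 * 4, sd = 10), c(n, 256, 4))
  lab <- rep(0:1, each = n / 2)
  tone <- 40 * sin(2 * pi * 6 * (0:255) / 256)
  for (i in which(lab == 1)) X[i, , ] <- X[i, , ] + tone
  cfg <- trainConfig(rngSeed = 4)

  m <- trainNn(buildCnn(4, rngSeed = 4), X, lab, cfg, epochs = 40)
  expect_lt(m$trainingLog$loss[40], m$trainingLog$loss[1])
  p <- predictProba(m, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(aucScore(p, lab, "roc"), 0.95)

  # identical windows give identical probabilities at inference
  Xsame <- X[c(1, 1), , , drop = FALSE]
  ps <- predictProba(m, Xsame)
  expect_equal(ps[1], ps[2])
  expect_error(predictProba(m, X[, , 1:2, drop = FALSE]), "channel count")
})

test_that("early stopping halts within patience of the best epoch", {
  set.seed(12)
  n <- 80
  X <- array(rnorm(n * 256 * 4, sd = 5), c(n, 256, 4))
  lab <- rep(0:1, n / 2)
  tone <- 30 * sin(2 * pi * 6 * (0:255) / 256)
  for (i in which(lab == 1)) X[i, , ] <- X[i, , ] + tone
  cfg <- trainConfig(rngSeed = 1, rnnMaxEpochs = 40, rnnPatience = 5)
  val <- list(windows = X[1:20, , ], labels = lab[1:20])
  m <- trainNn(buildRnn(4, rngSeed = 2), X, lab, cfg, validation = val)
  lg <- m$trainingLog
  expect_lte(lg$stopEpoch, lg$bestEpoch + 5)
  expect_error(trainNn(buildRnn(4), X, lab, cfg), "validation")
})

test_that("warm start reproduces the base model before any update", {
  set.seed(3)
  X <- array(rnorm(40 * 256 * 4, sd = 8), c(40, 256, 4))
  lab <- rep(0:1, 20)
  cfg <- trainConfig(rngSeed = 6)
  base <- trainNn(buildCnn(4, rngSeed = 6), X, lab, cfg, epochs = 2)
  warm <- trainNn(buildCnn(4, rngSeed = 99), X, lab, cfg, baseModel = base,
                  epochs = 0)
  expect_equal(predictProba(warm, X), predictProba(base, X))
})

test_that("lintanh inference stays close to tanh inference", {
  set.seed(21)
  X <- array(rnorm(30 * 256 * 4, sd = 12), c(30, 256, 4))
  lab <- rep(0:1, 15)
  m <- trainNn(buildCnn(4, rngSeed = 8), X, lab, trainConfig(rngSeed = 8),
               epochs = 3)
  pLin <- predictProba(m, X, linear = TRUE)
  pTanh <- predictProba(m, X, linear = FALSE)
  # regression-tested bound on the paired probability difference
  expect_lt(max(abs(pLin - pTanh)), 0.35)
})

test_that("probability smoothing is a shrinking-window moving median", {
  expect_equal(smoothProbs(c(0, 1, 0)), c(0, 0, 0))
  mono <- c(0.1, 0.2, 0.5, 0.7, 0.9)
  expect_equal(smoothProbs(mono), mono)
  expect_equal(smoothProbs(0.4), 0.4)
  expect_equal(smoothProbs(c(0.2, 0.9)), c(0.2, 0.9))
})
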