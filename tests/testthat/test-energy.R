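test_that("total energy applies the cost table to the ledger", {
  expect_equal(totalEnergy(opLedger("empty")), 0)
  led <- opLedger("x", load = 2, store = 1, float_add = 1)
  expect_equal(totalEnergy(led), 2 * 5 + 1 * 5 + 0.9)
  # MAC convention: one fused MAC costs E_add + E_mult = 4.6 pJ
  expect_equal(totalEnergy(opLedger("m", mac = 1)), 4.6)
  expect_error(opLedger("bad", banana = 3), "unknown operation class")
})

test_that("ledger arithmetic: additivity and scaling", {
  a <- opLedger("a", load = 3, mac = 7)
  b <- opLedger("b", store = 2, compare = 5)
  expect_equal(totalEnergy(a + b), totalEnergy(a) + totalEnergy(b))
  expect_equal(aoCount(scaleLedger(a, 4)), 4 * aoCount(a))
  # report total equals the sum over its components
  rep <- rfOpCounts()
  expect_equal(totalEnergy(rep),
               sum(vapply(rep@ledgers, totalEnergy, numeric(1))))
})

test_that("feature ledgers follow the documented counting rules", {
  m <- featureOpCounts("mean", 256)
  expect_equal(unname(m@counts[c("load", "float_add", "float_mult", "store")]),
               c(256, 255, 1, 1))
  mx <- featureOpCounts("maximum", 256)
  expect_equal(unname(mx@counts[c("load", "compare", "store")]), c(256, 255, 1))
  ll <- featureOpCounts("line_length", 256)
  expect_equal(unname(ll@counts[["float_add"]]), 255 + 254)
  expect_equal(unname(ll@counts[["compare"]]), 255)  # abs as sign test
  expect_equal(unname(ll@counts[["load"]]), 510)
  expect_error(featureOpCounts("nope"), "unknown feature")
})

test_that("conv layer counts match closed forms and a brute-force oracle", {
  rep <- cnnOpCounts(C = 4)
  expect_equal(macCount(rep, "conv1"), 232 * 15 * (4 * 25))  # 348000
  # 4-way max pooling: 3 compares per output value
  pool1 <- rep@ledgers[[which(vapply(rep@ledgers, slot, "", "component") ==
                                "poolconv1")]]
  expect_equal(unname(pool1@counts[["compare"]]), 15 * 58 * 3)

  # oracle: instrumented forward pass on a tiny architecture counting one
  # MAC per kernel weight per output position
  bruteConvMacs <- function(Tlen, K, Min, F) {
    n <- 0
    for (f in seq_len(F))
      for (j in seq_len(Tlen - K + 1))
        for (m in seq_len(Min))
          for (k in seq_len(K)) n <- n + 1
    n
  }
  tiny <- cnnOpCounts(C = 2, inputLength = 160)
  expect_equal(macCount(tiny, "conv1"), bruteConvMacs(160, 25, 2, 15))
  # shape chain too short for the kernels -> error naming the layer
  expect_error(cnnOpCounts(C = 2, inputLength = 40), "conv")
})

test_that("channel scaling is linear for features, constant for trees", {
  r4 <- rfOpCounts(C = 4)
  r8 <- rfOpCounts(C = 8)
  featAo <- function(rep) aoCount(rep) -
    aoCount(rep@ledgers[[length(rep@ledgers)]])
  expect_equal(featAo(r8), 2 * featAo(r4))
  tree4 <- r4@ledgers[[length(r4@ledgers)]]
  tree8 <- r8@ledgers[[length(r8@ledgers)]]
  expect_equal(tree4@counts, tree8@counts)
  expect_equal(unname(tree4@counts[["compare"]]), 100 * 10 + 1)
})

test_that("LSTM counts follow the recurrence arithmetic", {
  rep <- rnnOpCounts(C = 4)
  expect_equal(macCount(rep, "lstm"), 256 * 4 * (24 * 20))      # 491520
  expect_equal(macCount(rep, "time_distributed"), 256 * 400)    # 102400
  # C = 2 oracle via the standard parameter-count formula per step
  rep2 <- rnnOpCounts(C = 2)
  expect_equal(macCount(rep2, "lstm"), 256 * 4 * (22 * 20))
})

test_that("adding a layer or stage never decreases the totals", {
  cn <- cnnOpCounts()
  expect_gte(macCount(cn), macCount(cn, "conv"))
  expect_equal(macCount(cn, character(0)), 0)
  sub <- new("EnergyReport", detector = "cnn",
             ledgers = cn@ledgers[1:3], costs = cn@costs)
  expect_gt(totalEnergy(cn), totalEnergy(sub))
})

test_that("hardware calibration recovers linear relations", {
  est <- c(1, 2, 3.5, 5, 8, 10, 12.5, 15, 17, 20)
  fit <- suppressWarnings(calibrateHardware(est, 2 * est + 1))
  expect_equal(fit@slope, 2)
  expect_equal(fit@offset, 1)
  expect_equal(fit@adjR2, 1)
  expect_equal(fit@pearsonR, 1)

  ident <- suppressWarnings(calibrateHardware(est, est))
  expect_equal(ident@slope, 1)
  expect_equal(ident@offset, 0, tolerance = 1e-12)

  expect_error(calibrateHardware(rep(2, 5), 1:5), "zero variance")

  # Monte-Carlo coverage: slope within 3 SE in >= 95% of noisy replicates
  set.seed(31)
  hits <- vapply(1:200, function(i) {
    y <- 3 * est + 2 + rnorm(length(est), sd = 0.3)
    f <- calibrateHardware(est, y)
    se <- summary(f@fit)$coefficients["estimates", "Std. Error"]
    abs(f@slope - 3) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
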