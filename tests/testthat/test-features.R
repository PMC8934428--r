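test_that("time-domain features match direct evaluation of their formulas", {
  f <- timeFeatures(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["maximum"]], 4)
  expect_equal(f[["mad"]], 1)
  expect_equal(f[["variance"]], 1.25)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 1.64)
  expect_equal(f[["line_length"]], 3)

  # degenerate constant window
  g <- timeFeatures(rep(7, 256))
  expect_equal(unname(g[c("variance", "mad", "line_length", "entropy",
                          "skewness", "kurtosis")]), rep(0, 6))

  # shift invariance of the centered features
  set.seed(1)
  x <- rnorm(256, sd = 25)
  a <- timeFeatures(x)
  b <- timeFeatures(x + 1000)
  keep <- c("mad", "variance", "skewness", "kurtosis", "line_length")
  expect_equal(a[keep], b[keep])
})

test_that("power spectrum locates tones and satisfies Parseval's identity", {
  fs <- 256
  t <- (0:255) / fs
  ps <- powerSpectrum(sin(2 * pi * 10 * t), fs)
  expect_length(ps$power, 129)
  expect_equal(ps$df, 1)
  expect_equal(which.max(ps$power) - 1, 10)

  expect_true(all(powerSpectrum(rep(0, 256), fs)$power == 0))

  # sum of the one-sided spectrum (doubling interior bins) equals
  # N * windowPower * variance for white noise, within 5% over 100 seeds
  h <- 0.5 - 0.5 * cos(2 * pi * (0:255) / 256)
  ratios <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(256)
    p <- powerSpectrum(x, fs)$power
    twoSided <- p[1] + p[129] + 2 * sum(p[2:128])
    twoSided / (256 * sum((h * x)^2))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("frequency-domain features behave as their formulas dictate", {
  mk <- function(p) structure(list(power = p, freq = seq_along(p) - 1,
                                   df = 1), class = "PowerSpectrum")
  # point mass -> zero spectral entropy; uniform -> log2(L)
  L <- 129
  point <- numeric(L); point[20] <- 5
  expect_equal(suppressWarnings(freqFeatures(mk(point)))[["spectral_entropy"]],
               0)
  expect_equal(freqFeatures(mk(rep(2, L)))[["spectral_entropy"]], log2(L))

  # pure 20 Hz tone: beta band dominates, epileptogenicity index large
  x <- sin(2 * pi * 20 * (0:255) / 256)
  f <- freqFeatures(powerSpectrum(x, 256))
  expect_gt(f[["beta_power"]], 100 * (f[["theta_power"]] + f[["gamma_power"]]))
  expect_gt(f[["epi_index"]], 10)

  # all-zero spectrum guarded
  z <- freqFeatures(mk(numeric(L)))
  expect_equal(z[["spectral_entropy"]], 0)
  expect_equal(z[["epi_index"]], 0)
})

test_that("band power bins use inclusive integer limits", {
  mk <- function(p) structure(list(power = p, freq = seq_along(p) - 1,
                                   df = 1), class = "PowerSpectrum")
  p <- numeric(129)
  p[8 + 1] <- 1    # 8 Hz bin is shared by theta and alpha
  f <- freqFeatures(mk(p))
  expect_equal(f[["theta_power"]], 1)
  p2 <- numeric(129)
  p2[c(4, 8) + 1] <- 1
  expect_equal(freqFeatures(mk(p2))[["theta_power"]], 2)
  p3 <- numeric(129)
  p3[c(30, 45) + 1] <- 1
  expect_equal(suppressWarnings(freqFeatures(mk(p3)))[["gamma_power"]], 2)
})

test_that("extractFeatures concatenates equivariant per-channel blocks", {
  set.seed(4)
  w <- matrix(rnorm(256 * 4, sd = 15), 256, 4)
  v <- extractFeatures(w)
  expect_length(v, 64)
  expect_true(all(is.finite(v)))

  # identical channels -> identical blocks
  same <- extractFeatures(w[, c(1, 1, 1, 1)])
  expect_equal(unname(same[1:16]), unname(same[17:32]))

  # permuting channels permutes blocks
  perm <- extractFeatures(w[, c(2, 1, 3, 4)])
  expect_equal(unname(perm[1:16]), unname(v[17:32]))
  expect_equal(unname(perm[17:32]), unname(v[1:16]))
})

test_that("all 16 features stay finite on degenerate fuzz windows", {
  fuzz <- list(rep(0, 256), rep(1000, 256),
               c(1000, rep(0, 255)),                  # impulse
               seq(-1000, 1000, length.out = 256),    # +-1 mV ramp
               rep(c(-1000, 1000), 128))              # alternating extremes
  for (x in fuzz) {
    v <- suppressWarnings(
      c(timeFeatures(x), freqFeatures(powerSpectrum(x, 256))))
    expect_length(v, 16)
    expect_true(all(is.finite(v)))
  }
})

test_that("features are stable to window phase for stationary input", {
  set.seed(8)
  x <- as.numeric(stats::filter(rnorm(4096), rep(1, 4) / 4, sides = 1))
  x[is.na(x)] <- 0
  v1 <- timeFeatures(x[1:256])[["variance"]]
  vs <- vapply(seq(1, 2048, by = 128), function(s)
    timeFeatures(x[s:(s + 255)])[["variance"]], numeric(1))
  expect_lt(stats::sd(vs) / mean(vs), 0.5)  # same order of magnitude
})
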