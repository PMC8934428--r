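test_that("bandpass attenuates the stopband and passes the passband", {
  # 60 Hz lies beyond the 48 Hz stopband edge: >= 40 dB down. 10 Hz is in
  # the passband: within 1 dB. Steady state measured after a 1 s transient.
  in60 <- sineRecording(60)
  out60 <- bandpassFilter(in60)
  att <- 20 * log10(steadyRms(out60) / steadyRms(in60))
  expect_lte(att, -40)

  in10 <- sineRecording(10)
  out10 <- bandpassFilter(in10)
  gain <- 20 * log10(steadyRms(out10) / steadyRms(in10))
  expect_lt(abs(gain), 1)

  zero <- eegRecording(matrix(0, 512, 5), 256)
  expect_equal(eegSamples(bandpassFilter(zero)),
               eegSamples(zero), ignore_attr = TRUE)
})

test_that("bandpass design errors out when the band does not fit", {
  rec <- eegRecording(matrix(rnorm(100 * 2), ncol = 2), 64)
  expect_error(bandpassFilter(rec), "Nyquist")
})

test_that("high-amplitude rejection marks the right 1 s periods", {
  fs <- 256
  x <- matrix(rnorm(fs * 10 * 5, sd = 20), ncol = 5)
  x[round(5.3 * fs), 2] <- 1500   # one sample at +1.5 mV at t = 5.3 s
  rec <- eegRecording(x, fs)
  rej <- rejectHighAmplitude(rec)
  m <- validMask(rej)
  expect_true(all(!m[(5 * fs + 1):(6 * fs)]))
  expect_true(all(m[-((5 * fs + 1):(6 * fs))]))

  # idempotent
  expect_identical(validMask(rejectHighAmplitude(rej)), m)

  # boundary: exactly 1000 uV is retained (strict inequality)
  x2 <- matrix(0, fs * 2, 5)
  x2[10, 1] <- 1000
  expect_true(all(validMask(rejectHighAmplitude(eegRecording(x2, fs)))))

  # all within +-140 uV: nothing removed
  x3 <- matrix(runif(fs * 4 * 5, -140, 140), ncol = 5)
  expect_true(all(validMask(rejectHighAmplitude(eegRecording(x3, fs)))))
})

test_that("central re-referencing yields C-1 common-mode-free channels", {
  x <- matrix(rnorm(256 * 5, sd = 10), ncol = 5)
  rec <- eegRecording(x, 256)
  ref <- rereference(rec)
  expect_equal(nChannels(ref), 4)

  # identical electrodes -> all-zero output
  same <- eegRecording(matrix(rep(rnorm(256), 5), ncol = 5), 256)
  expect_true(all(abs(eegSamples(rereference(same))) < 1e-12))

  # common-mode offset rejection
  off <- eegRecording(x + 42, 256)
  expect_equal(eegSamples(rereference(off)), eegSamples(ref),
               ignore_attr = TRUE)

  # linearity
  sc <- eegRecording(3 * x, 256)
  expect_equal(eegSamples(rereference(sc)), 3 * eegSamples(ref),
               ignore_attr = TRUE)

  expect_error(rereference(rec, "nope"), "unknown central")
  expect_error(rereference(ref), "already")
})

test_that("invalid segments are excluded from all windowing", {
  rec <- makeTinyRecord(duration = 20, seizures = list(), seed = 2)$recording
  fs <- samplingRate(rec)
  mask <- validMask(rec)
  mask[(10 * fs + 1):(12 * fs)] <- FALSE   # invalidate seconds 10-12
  rec@validMask <- mask
  fm <- featureMatrix(rereference(dropInvalid(rec)), NULL)
  expect_false(any(fm$start >= 10 & fm$start < 12))

  # fully invalid recording: empty output without crashing
  rec@validMask[] <- FALSE
  fm0 <- featureMatrix(rereference(dropInvalid(rec)), NULL)
  expect_equal(nrow(fm0), 0)
})

test_that("the pipeline preserves the ictal rhythm through re-referencing", {
  out <- makeTinyRecord(duration = 20, seizures = list(c(8, 13)), seed = 21)
  pre <- preprocess(out$recording)
  expect_equal(nChannels(pre), 4)
  fm <- featureMatrix(pre, out$annotations)
  theta <- fm[, grep("theta_power", names(fm))[1]]
  expect_gt(mean(theta[fm$ictal == 1]), 5 * mean(theta[fm$ictal == 0]))
})
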