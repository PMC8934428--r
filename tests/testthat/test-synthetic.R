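test_that("generator is deterministic and honors the annotation contract", {
  cfg <- syntheticConfig(duration = 20, seizureIntervals = list(c(5, 9)),
                         rngSeed = 42)
  a <- generateRecording(cfg)
  b <- generateRecording(cfg)
  expect_identical(eegSamples(a$recording), eegSamples(b$recording))
  expect_equal(a$annotations$onset, 5)
  expect_equal(a$annotations$offset, 9)

  none <- generateRecording(syntheticConfig(duration = 10, rngSeed = 1))
  expect_equal(nrow(none$annotations), 0)
  starts <- seq(0, 9)
  expect_true(all(windowLabels(starts, none$annotations) == 0L))
})

test_that("overlapping or out-of-range seizure intervals are rejected", {
  expect_error(syntheticConfig(duration = 30,
                               seizureIntervals = list(c(5, 12), c(10, 15))),
               "non-overlapping")
  expect_error(syntheticConfig(duration = 10,
                               seizureIntervals = list(c(5, 12))),
               "within")
  expect_error(syntheticConfig(duration = 10, ictalBand = c(100, 140)),
               "twice")
})

test_that("interictal background is zero-mean and at uV scale", {
  rec <- makeTinyRecord(duration = 20, seizures = list(), seed = 3)$recording
  x <- eegSamples(rec)
  expect_lt(abs(mean(x)), 1)
  rms <- apply(x, 2, rmsOf)
  expect_true(all(rms > 10 & rms < 100))
})

test_that("ictal windows carry more band power than interictal windows", {
  # Monte-Carlo over seeds: theta band power (via the features module) must
  # separate annotated ictal seconds from background in nearly every run.
  hits <- vapply(1:50, function(s) {
    out <- makeTinyRecord(duration = 20, seizures = list(c(8, 13)), seed = s)
    fm <- featureMatrix(rereference(out$recording), out$annotations)
    theta <- fm[, grep("theta_power", names(fm))[1]]
    mean(theta[fm$ictal == 1]) > mean(theta[fm$ictal == 0])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("every annotated ictal second overlaps the rhythmic component", {
  out <- makeTinyRecord(duration = 25, seizures = list(c(6, 11), c(18, 22)),
                        seed = 9)
  quiet <- makeTinyRecord(duration = 25, seizures = list(c(6, 11), c(18, 22)),
                          seed = 9, ictalAmplitude = 0)
  diffSig <- eegSamples(out$recording) - eegSamples(quiet$recording)
  fs <- samplingRate(out$recording)
  for (i in seq_len(nrow(out$annotations))) {
    sec <- floor(out$annotations$onset[i]):(ceiling(out$annotations$offset[i]) - 1)
    for (s in sec) {
      idx <- (s * fs + 1):((s + 1) * fs)
      expect_gt(max(abs(diffSig[idx, 1])), 0)
    }
  }
})

test_that("artifact injection is controlled by rate and amplitude", {
  rec <- makeTinyRecord(duration = 30, seizures = list(), seed = 5)$recording
  none <- injectArtifacts(rec, rate = 0, amplitude = 2000)
  expect_identical(eegSamples(none$recording), eegSamples(rec))

  big <- injectArtifacts(rec, rate = 2000, amplitude = 2000, rngSeed = 7)
  expect_gt(length(big$artifactTimes), 0)
  expect_gt(max(abs(eegSamples(big$recording))), 1000)
  rej <- rejectHighAmplitude(big$recording)
  expect_gt(sum(!validMask(rej)), 0)

  small <- injectArtifacts(rec, rate = 2000, amplitude = 140, rngSeed = 7)
  expect_gt(length(small$artifactTimes), 0)
  expect_lt(max(abs(eegSamples(small$recording))), 1000)
  rej2 <- rejectHighAmplitude(small$recording)
  expect_identical(validMask(rej2), validMask(small$recording))
})
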