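# Small fixtures shared across the suite, built in code.

# short annotated synthetic record (default: one 5 s seizure in 30 s)
makeTinyRecord <- function(duration = 30, seizures = list(c(12, 17)),
                           seed = 11, ...) {
  generateRecording(syntheticConfig(duration = duration,
                                    seizureIntervals = seizures,
                                    rngSeed = seed, ...))
}

# pure sinusoid recording on all electrodes
sineRecording <- function(freq, duration = 5, fs = 256, nElectrodes = 5,
                          amplitude = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amplitude * sin(2 * pi * freq * t)
  eegRecording(matrix(rep(x, nElectrodes), ncol = nElectrodes), fs)
}

rmsOf <- function(x) sqrt(mean(x^2))

# steady-state RMS after discarding the first second of transient
steadyRms <- function(recording, channel = 1) {
  fs <- samplingRate(recording)
  x <- eegSamples(recording)[-(seq_len(fs)), channel]
  rmsOf(x)
}
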