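#' Configuration for the synthetic EEG generator
#'
#' Defines the statistical structure of a simulated multichannel EEG record:
#' a 1/f-like interictal background at microvolt scale on every electrode,
#' plus, inside each annotated seizure interval, a rhythmic amplitude-modulated
#' component with slowly evolving frequency inside `ictalBand`. The default
#' montage is five electrodes sampled at 256 Hz, with the middle electrode
#' designated central, emulating a subgaleal-style layout over the seizure
#' onset zone.
#'
#' @param duration record length in seconds.
#' @param seizureIntervals data.frame or list of `c(onset, offset)` pairs (s);
#'   must be non-overlapping and inside `[0, duration]`.
#' @param samplingRate sampling rate in Hz (default 256).
#' @param nElectrodes electrode count (default 5).
#' @param ictalBand numeric length-2, low/high edge in Hz of the seizure
#'   rhythm (default 4-8 Hz, the theta band).
#' @param ictalAmplitude peak amplitude in uV of the ictal rhythm on
#'   peripheral electrodes (default 80; the central electrode receives half,
#'   so central re-referencing retains the rhythm).
#' @param backgroundRms target RMS in uV of the interictal background
#'   (default 20, typical of surface EEG).
#' @param backgroundExponent spectral slope of the 1/f^a background
#'   (default 1).
#' @param artifactRate high-amplitude artifact events per hour (default 0;
#'   artifacts can also be added afterwards with [injectArtifacts()]).
#' @param artifactAmplitude artifact peak amplitude in uV (default 2000,
#'   i.e. above the 1 mV rejection threshold).
#' @param rngSeed integer seed; identical configurations and seeds give
#'   bitwise-identical records.
#' @return a validated list of class `SyntheticConfig`.
#' @examples
#' cfg <- syntheticConfig(duration = 60, seizureIntervals = list(c(20, 30)))
#' @export
syntheticConfig <- function(duration,
                            seizureIntervals = list(),
                            samplingRate = 256,
                            nElectrodes = 5,
                            ictalBand = c(4, 8),
                            ictalAmplitude = 80,
                            backgroundRms = 20,
                            backgroundExponent = 1,
                            artifactRate = 0,
                            artifactAmplitude = 2000,
                            rngSeed = 1L) {
  if (is.data.frame(seizureIntervals))
    seizureIntervals <- lapply(seq_len(nrow(seizureIntervals)),
      function(i) c(seizureIntervals$onset[i], seizureIntervals$offset[i]))
  ann <- if (length(seizureIntervals))
    seizureAnnotations(vapply(seizureIntervals, `[`, numeric(1), 1),
                       vapply(seizureIntervals, `[`, numeric(1), 2))
  else seizureAnnotations(data.frame(onset = numeric(), offset = numeric()))
  if (nrow(ann) && (min(ann$onset) < 0 || max(ann$offset) > duration))
    stop("seizure intervals must lie within [0, duration]")
  stopifnot(length(ictalBand) == 2, ictalBand[1] < ictalBand[2])
  if (samplingRate <= 2 * ictalBand[2])
    stop("samplingRate must exceed twice the upper ictal band edge")
  stopifnot(duration > 0, nElectrodes >= 2, backgroundRms > 0,
            ictalAmplitude >= 0, artifactRate >= 0, artifactAmplitude > 0)
  structure(list(
    duration = duration, seizureIntervals = ann,
    samplingRate = samplingRate, nElectrodes = nElectrodes,
    ictalBand = ictalBand, ictalAmplitude = ictalAmplitude,
    backgroundRms = backgroundRms, backgroundExponent = backgroundExponent,
    artifactRate = artifactRate, artifactAmplitude = artifactAmplitude,
    rngSeed = as.integer(rngSeed)), class = "SyntheticConfig")
}

# deterministic substream derivation, kept inside 32-bit integer range
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483647)
}

# 1/f^a colored noise by frequency-domain shaping of white Gaussian noise,
# scaled to a target RMS.
.coloredNoise <- function(n, exponent, rms) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                  # fold to two-sided frequency index
  f[1] <- 1                            # DC treated like the first bin
  shape <- f^(-exponent / 2)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (rms / sqrt(mean(x^2)))
}

# Amplitude-modulated linear chirp spanning the middle of the ictal band,
# with a Tukey-style onset/offset taper.
.ictalWaveform <- function(nSamp, fs, band, amplitude, phase = 0) {
  t <- (seq_len(nSamp) - 1) / fs
  dur <- nSamp / fs
  f0 <- band[1] + 0.2 * diff(band)
  f1 <- band[2] - 0.2 * diff(band)
  inst <- f0 + (f1 - f0) * t / dur               # linear chirp
  ph <- phase + 2 * pi * cumsum(inst) / fs
  env <- rep(1, nSamp)
  ramp <- max(2L, min(round(0.5 * fs), floor(nSamp / 4)))
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  env[seq_len(ramp)] <- up
  env[nSamp + 1 - seq_len(ramp)] <- up
  # slow amplitude modulation, as ictal discharges wax and wane
  env <- env * (0.8 + 0.2 * sin(2 * pi * 0.5 * t))
  amplitude * env * sin(ph)
}

#' Generate an annotated synthetic EEG recording
#'
#' Simulates zero-mean colored-noise background with spectral density
#' proportional to 1/f^a on every electrode, and adds, inside each configured
#' seizure interval, a rhythmic chirp in the ictal band on all electrodes
#' (full weight on peripherals, half weight on the central electrode, so the
#' rhythm survives central re-referencing). Deterministic given the seed; the
#' seed is expanded into independent substreams per electrode and component,
#' so e.g. adding artifacts later does not perturb the background.
#'
#' @param config a [syntheticConfig()].
#' @return list with `recording` (an [EegRecording-class]) and `annotations`
#'   (data.frame of onset/offset, one row per seizure).
#' @examples
#' out <- generateRecording(syntheticConfig(duration = 30,
#'   seizureIntervals = list(c(10, 15)), rngSeed = 7))
#' out$annotations
#' @export
generateRecording <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  fs <- config$samplingRate
  n <- round(config$duration * fs)
  E <- config$nElectrodes
  central <- ceiling(E / 2)

  samples <- matrix(0, n, E)
  for (e in seq_len(E)) {
    set.seed(.substream(config$rngSeed, 1000 * e))
    samples[, e] <- .coloredNoise(n, config$backgroundExponent,
                                  config$backgroundRms)
  }

  ann <- config$seizureIntervals
  if (nrow(ann)) {
    for (s in seq_len(nrow(ann))) {
      i0 <- floor(ann$onset[s] * fs) + 1L
      i1 <- min(n, ceiling(ann$offset[s] * fs))
      set.seed(.substream(config$rngSeed, 7919 * s))
      phase <- stats::runif(1, 0, 2 * pi)
      wav <- .ictalWaveform(i1 - i0 + 1L, fs, config$ictalBand,
                            config$ictalAmplitude, phase)
      w <- rep(1, E); w[central] <- 0.5
      samples[i0:i1, ] <- samples[i0:i1, ] + outer(wav, w)
    }
  }

  rec <- eegRecording(samples, fs,
                      channelNames = paste0("E", seq_len(E)),
                      centralChannel = paste0("E", central))
  if (config$artifactRate > 0) {
    inj <- injectArtifacts(rec, config$artifactRate,
                           config$artifactAmplitude,
                           rngSeed = config$rngSeed + 523L)
    rec <- inj$recording
  }
  list(recording = rec, annotations = ann)
}

#' Inject short high-amplitude artifacts
#'
#' Adds brief (< 0.1 s) high-amplitude transients at Poisson-distributed times
#' on all electrodes, emulating sharp non-cerebral artifacts that the
#' preprocessing chain is expected to reject when they exceed 1 mV.
#'
#' @param recording an [EegRecording-class].
#' @param rate expected events per hour.
#' @param amplitude peak amplitude of each transient in uV (> 0).
#' @param rngSeed integer seed for the artifact substream.
#' @return list with `recording` (signal plus artifacts) and `artifactTimes`
#'   (numeric vector of event times in seconds; the count side channel for
#'   assertions).
#' @examples
#' rec <- generateRecording(syntheticConfig(duration = 30))$recording
#' out <- injectArtifacts(rec, rate = 600, amplitude = 2000, rngSeed = 2)
#' length(out$artifactTimes)
#' @export
injectArtifacts <- function(recording, rate, amplitude, rngSeed = 1L) {
  stopifnot(is(recording, "EegRecording"), amplitude > 0, rate >= 0)
  if (rate == 0)
    return(list(recording = recording, artifactTimes = numeric()))
  fs <- recording@samplingRate
  n <- nrow(recording@samples)
  hours <- n / fs / 3600
  set.seed(as.integer(rngSeed))
  k <- stats::rpois(1, rate * hours)
  if (k == 0)
    return(list(recording = recording, artifactTimes = numeric()))
  times <- sort(stats::runif(k, 0, n / fs))
  width <- round(0.05 * fs)                     # 50 ms transient
  pulse <- amplitude * exp(-0.5 * ((seq_len(width) - width / 2) / (width / 8))^2)
  samples <- recording@samples
  for (tt in times) {
    i0 <- floor(tt * fs) + 1L
    idx <- i0:min(n, i0 + width - 1L)
    samples[idx, ] <- samples[idx, ] + pulse[seq_along(idx)]
  }
  out <- recording
  out@samples <- samples
  list(recording = out, artifactTimes = times)
}
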