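#' Feature names
#'
#' Fixed ordering of the 16 per-channel features: eight time-domain
#' (maximum, mean, mean absolute deviation, variance, skewness, kurtosis,
#' line length, amplitude entropy) followed by eight frequency-domain
#' (spectral entropy, mean/max/variance of the power spectrum, theta, beta
#' and gamma band power, epileptogenicity index).
#'
#' @return character vector of length 16.
#' @export
featureNames <- function() {
  c("maximum", "mean", "mad", "variance", "skewness", "kurtosis",
    "line_length", "entropy",
    "spectral_entropy", "mean_power", "max_power", "power_variance",
    "theta_power", "beta_power", "gamma_power", "epi_index")
}

# Band edges in Hz; the printed inclusive summation limits share boundary
# bins (8 Hz in both theta and alpha, etc.) and are kept as such.
.bands <- list(theta = c(4, 8), alpha = c(8, 13),
               beta = c(13, 30), gamma = c(30, 45))

#' Time-domain features of one window
#'
#' Computes the eight time-domain features of a 1 s window on one channel.
#' All statistics use the 1/N convention; skewness and kurtosis are
#' normalized by the population standard deviation (and return 0 for a
#' constant window, where they are undefined). Line length is the sum of
#' absolute successive differences. Amplitude entropy is the Shannon entropy
#' (base 2) of a 16-bin histogram of the window's samples over
#' `[min, max]`, with `0 log 0 := 0`.
#'
#' The zero-mean samples and their squares are computed once and shared
#' across the moment-based features, mirroring how an embedded
#' implementation amortizes them.
#'
#' @param x numeric vector of window samples (uV), length >= 2.
#' @param entropyBins histogram bin count for the amplitude entropy.
#' @return named numeric vector of 8 features.
#' @examples
#' timeFeatures(c(1, 2, 3, 4))
#' @export
timeFeatures <- function(x, entropyBins = 16) {
  n <- length(x)
  stopifnot(n >= 2)
  m <- mean(x)
  centered <- x - m                 # shared intermediate
  squares <- centered^2             # shared intermediate
  v <- sum(squares) / n
  s <- sqrt(v)
  if (s > 0) {
    skew <- sum(squares * centered) / (n * s^3)
    kurt <- sum(squares * squares) / (n * v^2)
  } else {
    skew <- 0
    kurt <- 0
  }
  rng <- range(x)
  if (rng[2] > rng[1]) {
    bins <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * entropyBins),
                 entropyBins - 1)
    p <- tabulate(bins + 1L, nbins = entropyBins) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  } else {
    ent <- 0
  }
  c(maximum = max(x), mean = m,
    mad = sum(abs(centered)) / n,
    variance = v, skewness = skew, kurtosis = kurt,
    line_length = sum(abs(diff(x))),
    entropy = ent)
}

#' One-sided power spectrum of a window
#'
#' Applies a Hann window and returns the squared magnitudes of the one-sided
#' DFT: `L = N/2 + 1` bins (129 for a 256-sample window) with bin width
#' `1/T_w` (1 Hz for a 1 s window). No interior-bin doubling is applied; band
#' ratios and spectral entropies are invariant to that convention, and band
#' powers adopt it as the package's fixed scale.
#'
#' @param x numeric window samples, length N.
#' @param samplingRate sampling rate in Hz.
#' @return object of class `PowerSpectrum`: list with `power` (length L),
#'   `freq` (Hz) and `df` (bin width, Hz).
#' @examples
#' ps <- powerSpectrum(sin(2 * pi * 10 * (0:255) / 256), 256)
#' ps$freq[which.max(ps$power)]  # 10 Hz
#' @export
powerSpectrum <- function(x, samplingRate = 256) {
  n <- length(x)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)   # periodic Hann
  X <- stats::fft(x * h)
  L <- n %/% 2 + 1
  p <- Mod(X[seq_len(L)])^2
  structure(list(power = p,
                 freq = (seq_len(L) - 1) * samplingRate / n,
                 df = samplingRate / n),
            class = "PowerSpectrum")
}

# inclusive bin sum from f1 to f2 (Hz); bins indexed from 0 at DC
.bandPower <- function(ps, band) {
  i <- which(ps$freq >= band[1] & ps$freq <= band[2])
  sum(ps$power[i])
}

#' Frequency-domain features of a power spectrum
#'
#' Spectral entropy (base-2 Shannon entropy of the normalized spectrum),
#' mean, maximum and variance of the bin powers (1/L convention), band powers
#' over theta (4-8 Hz), beta (13-30 Hz) and gamma (30-45 Hz), and the
#' epileptogenicity index `(P_beta + P_gamma) / (P_theta + P_alpha)` where
#' alpha (8-13 Hz) is computed internally. Band sums use inclusive bin limits,
#' so adjacent bands share their boundary bin. An all-zero spectrum yields
#' entropy 0 and index 0 (guarded, with a warning for the index's zero
#' denominator).
#'
#' @param ps a [powerSpectrum()] result.
#' @return named numeric vector of 8 features.
#' @export
freqFeatures <- function(ps) {
  stopifnot(inherits(ps, "PowerSpectrum"))
  P <- ps$power
  L <- length(P)
  tot <- sum(P)
  if (tot > 0) {
    p <- P[P > 0] / tot
    sent <- -sum(p * log2(p))
  } else {
    sent <- 0
  }
  mp <- mean(P)
  bp <- vapply(.bands, .bandPower, numeric(1), ps = ps)
  denom <- bp[["theta"]] + bp[["alpha"]]
  if (denom > 0) {
    epi <- (bp[["beta"]] + bp[["gamma"]]) / denom
  } else {
    if (bp[["beta"]] + bp[["gamma"]] > 0)
      warning("zero theta+alpha power; epileptogenicity index set to 0")
    epi <- 0
  }
  c(spectral_entropy = sent, mean_power = mp, max_power = max(P),
    power_variance = sum((P - mp)^2) / L,
    theta_power = bp[["theta"]], beta_power = bp[["beta"]],
    gamma_power = bp[["gamma"]], epi_index = epi)
}

#' Extract the 16-feature vector of one multichannel window
#'
#' Computes all 16 features per channel on a complete 1 s window and
#' concatenates them in fixed channel order; a 4-channel montage yields a
#' 64-element vector named `<channel>_<feature>`.
#'
#' @param window numeric matrix, samples x channels (one 1 s window).
#' @param samplingRate sampling rate in Hz.
#' @return named numeric vector of length `16 * ncol(window)`.
#' @examples
#' w <- matrix(rnorm(256 * 4), 256, 4)
#' length(extractFeatures(w))  # 64
#' @export
extractFeatures <- function(window, samplingRate = 256) {
  window <- as.matrix(window)
  chn <- colnames(window)
  if (is.null(chn)) chn <- paste0("ch", seq_len(ncol(window)))
  out <- lapply(seq_len(ncol(window)), function(ci) {
    x <- window[, ci]
    f <- c(timeFeatures(x), freqFeatures(powerSpectrum(x, samplingRate)))
    names(f) <- paste0(chn[ci], "_", names(f))
    f
  })
  unlist(out)
}

# 1 s non-overlapping window start indices that avoid invalid samples
.validWindowStarts <- function(recording, windowSamples) {
  n <- nrow(recording@samples)
  starts <- seq(1L, n - windowSamples + 1L, by = windowSamples)
  ok <- vapply(starts, function(s)
    all(recording@validMask[s:(s + windowSamples - 1L)]), logical(1))
  starts[ok]
}

#' Feature matrix over a recording
#'
#' Slides a non-overlapping 1 s window over a (preprocessed, re-referenced)
#' recording and extracts the per-window feature vector. Windows overlapping
#' invalid samples are skipped. Each row is labelled ictal if its start time
#' falls inside an annotated seizure.
#'
#' @param recording an [EegRecording-class].
#' @param annotations seizure annotation data.frame (onset/offset in s).
#' @return data.frame with columns `start` (s), `ictal` (0/1) and the
#'   `16 * C` feature columns.
#' @export
featureMatrix <- function(recording, annotations = NULL) {
  fs <- recording@samplingRate
  nw <- round(fs)                      # 1 s windows
  starts <- .validWindowStarts(recording, nw)
  if (!length(starts)) {
    return(data.frame(start = numeric(), ictal = integer()))
  }
  feats <- t(vapply(starts, function(s)
    extractFeatures(recording@samples[s:(s + nw - 1L), , drop = FALSE], fs),
    numeric(16L * ncol(recording@samples))))
  tsec <- (starts - 1) / fs
  lab <- windowLabels(tsec, annotations)
  out <- data.frame(start = tsec, ictal = lab)
  cbind(out, as.data.frame(feats))
}

#' Label 1 s windows against seizure annotations
#'
#' A window is ictal iff its start time lies inside `[onset, offset)` of any
#' annotated seizure.
#'
#' @param starts numeric vector of window start times (s).
#' @param annotations data.frame with onset/offset columns, or NULL.
#' @return integer vector of 0/1 labels.
#' @export
windowLabels <- function(starts, annotations = NULL) {
  lab <- integer(length(starts))
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      lab[starts >= annotations$onset[i] & starts < annotations$offset[i]] <- 1L
    }
  }
  lab
}
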