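#' Bandpass filter specification
#'
#' The signal-conditioning filter of the online detector front end: a 10th
#' order Chebyshev type-II IIR bandpass with 40 dB stopband attenuation and
#' stopband edges at 0.1 and 48 Hz, which suppresses drift, power-line noise
#' and broad-band muscle activity in one pass.
#'
#' @param order filter order (default 10; must be even).
#' @param stopbandLow,stopbandHigh stopband edge frequencies in Hz.
#' @param stopbandAttenuation stopband attenuation in dB.
#' @return list of class `FilterSpec`.
#' @export
filterSpec <- function(order = 10, stopbandLow = 0.1, stopbandHigh = 48,
                       stopbandAttenuation = 40) {
  stopifnot(order %% 2 == 0, stopbandLow < stopbandHigh,
            stopbandAttenuation > 0)
  structure(list(order = order, stopbandLow = stopbandLow,
                 stopbandHigh = stopbandHigh,
                 stopbandAttenuation = stopbandAttenuation),
            class = "FilterSpec")
}

# Design the bandpass and factor it into second-order sections (conjugate
# pole/zero pairing, nearest-neighbour zero assignment). Causal single-pass
# realization, as an embedded online detector would run it.
.designSos <- function(spec, fs) {
  if (spec$stopbandHigh >= fs / 2)
    stop("stopband high edge must be below the Nyquist frequency")
  fl <- signal::cheby2(spec$order / 2, spec$stopbandAttenuation,
                       c(spec$stopbandLow, spec$stopbandHigh) / (fs / 2),
                       type = "pass")
  b <- fl$b; a <- fl$a
  p <- polyroot(rev(a)); z <- polyroot(rev(b))
  if (any(Mod(p) >= 1))
    stop(sprintf(
      "unstable bandpass design at fs=%g Hz (max pole modulus %.6f)",
      fs, max(Mod(p))))
  pairConj <- function(r) {
    used <- rep(FALSE, length(r)); out <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      j <- which(!used & abs(r - Conj(r[i])) < 1e-6)[1]
      if (!is.na(j)) { used[j] <- TRUE; out[[length(out) + 1]] <- c(r[i], r[j]) }
      else out[[length(out) + 1]] <- r[i]
    }
    out
  }
  pp <- pairConj(p); zz <- pairConj(z)
  pc <- vapply(pp, function(q) mean(Mod(q)), numeric(1))
  zc <- vapply(zz, function(q) mean(Mod(q)), numeric(1))
  usedz <- rep(FALSE, length(zz))
  sos <- vector("list", length(pp))
  for (i in order(-pc)) {
    d <- abs(zc - pc[i]); d[usedz] <- Inf
    j <- which.min(d); usedz[j] <- TRUE
    sos[[i]] <- list(b = Re(signal::poly(zz[[j]])),
                     a = Re(signal::poly(pp[[i]])))
  }
  list(sos = sos, gain = b[1] / a[1])
}

#' Bandpass-filter a recording
#'
#' Applies the Chebyshev type-II bandpass of `spec` to every channel as a
#' causal single pass through cascaded second-order sections. Output length
#' equals input length; the validity mask is carried through unchanged.
#'
#' @param recording an [EegRecording-class].
#' @param spec a [filterSpec()].
#' @return the filtered [EegRecording-class].
#' @examples
#' rec <- generateRecording(syntheticConfig(duration = 10))$recording
#' filt <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(recording, spec = filterSpec()) {
  stopifnot(is(recording, "EegRecording"))
  design <- .designSos(spec, recording@samplingRate)
  out <- recording
  for (ch in seq_len(ncol(out@samples))) {
    y <- out@samples[, ch] * design$gain
    for (s in design$sos) y <- as.numeric(signal::filter(s$b, s$a, y))
    out@samples[, ch] <- y
  }
  out
}

#' Exclude invalid segments
#'
#' Propagates the validity mask: samples flagged invalid (e.g. electrode
#' deficiency, impedance measurement) are zeroed and stay excluded from all
#' downstream windowing. The mask itself is the exclusion contract; windowing
#' functions skip any window overlapping an invalid sample.
#'
#' @param recording an [EegRecording-class].
#' @return the recording with invalid samples zeroed and mask preserved.
#' @export
dropInvalid <- function(recording) {
  stopifnot(is(recording, "EegRecording"))
  out <- recording
  out@samples[!out@validMask, ] <- 0
  out
}

#' Reject high-amplitude periods
#'
#' Marks every contiguous period of `period` seconds that contains any sample
#' with absolute amplitude strictly above `threshold` (default 1 mV = 1000 uV,
#' on any electrode) as invalid. The period grid is aligned to the 1 s
#' analysis-window grid. Idempotent; samples themselves are untouched.
#'
#' @param recording an [EegRecording-class].
#' @param threshold rejection threshold in uV (strict inequality; a sample at
#'   exactly the threshold is retained).
#' @param period grid period in seconds.
#' @return the recording with an updated validity mask.
#' @export
rejectHighAmplitude <- function(recording, threshold = 1000, period = 1) {
  stopifnot(is(recording, "EegRecording"), threshold > 0, period > 0)
  fs <- recording@samplingRate
  n <- nrow(recording@samples)
  per <- round(period * fs)
  mask <- recording@validMask
  hit <- apply(abs(recording@samples) > threshold, 1, any)
  if (any(hit)) {
    bad <- unique((which(hit) - 1L) %/% per)
    for (bk in bad) {
      idx <- (bk * per + 1L):min(n, (bk + 1L) * per)
      mask[idx] <- FALSE
    }
  }
  out <- recording
  out@validMask <- mask
  out
}

#' Re-reference to the central electrode
#'
#' Subtracts the centrally positioned electrode from each peripheral
#' electrode, yielding C = E - 1 referenced channels (4 for the default
#' 5-electrode montage) and cancelling any common-mode component.
#'
#' @param recording an [EegRecording-class] (not yet referenced).
#' @param centralLabel label of the central electrode; defaults to the
#'   recording's designated central channel.
#' @return a re-referenced [EegRecording-class] with `referenced = TRUE` and
#'   channels named `<peripheral>-<central>`.
#' @examples
#' rec <- generateRecording(syntheticConfig(duration = 5))$recording
#' nChannels(rereference(rec))  # 4
#' @export
rereference <- function(recording, centralLabel = NULL) {
  stopifnot(is(recording, "EegRecording"))
  if (recording@referenced) stop("recording is already re-referenced")
  if (is.null(centralLabel)) centralLabel <- recording@centralChannel
  ci <- match(centralLabel, recording@channelNames)
  if (is.na(ci)) stop("unknown central electrode label: ", centralLabel)
  periph <- setdiff(seq_len(ncol(recording@samples)), ci)
  samples <- recording@samples[, periph, drop = FALSE] -
    recording@samples[, ci]
  eegRecording(samples, recording@samplingRate,
    channelNames = paste0(recording@channelNames[periph], "-", centralLabel),
    validMask = recording@validMask, referenced = TRUE)
}

#' Run the full preprocessing chain
#'
#' Fixed order: invalid-segment exclusion, bandpass filtering,
#' high-amplitude artifact rejection (per electrode, pre-reference), central
#' re-referencing. This is the conditioning every detector input goes
#' through.
#'
#' @param recording an [EegRecording-class].
#' @param spec a [filterSpec()].
#' @param threshold rejection threshold in uV.
#' @param centralLabel central electrode label (defaults to the designated
#'   one).
#' @return a re-referenced, filtered [EegRecording-class].
#' @export
preprocess <- function(recording, spec = filterSpec(), threshold = 1000,
                       centralLabel = NULL) {
  rec <- dropInvalid(recording)
  rec <- bandpassFilter(rec, spec)
  rec <- rejectHighAmplitude(rec, threshold = threshold)
  rereference(rec, centralLabel)
}
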