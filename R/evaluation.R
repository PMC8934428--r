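#' Area under the ROC or precision-recall curve
#'
#' Threshold-free window-level metrics over the per-second probability
#' series. The ROC area is the pairwise concordance statistic (ties counted
#' half); the PR area uses step integration over all observed thresholds
#' (precision at each recall increment), the convention of standard ML
#' toolkits for imbalanced detection tasks.
#'
#' @param probs numeric probability series.
#' @param labels 0/1 window labels, same length.
#' @param curve `"roc"` or `"pr"`.
#' @return the area, in `[0, 1]`.
#' @examples
#' aucScore(c(.1, .4, .35, .8), c(0, 0, 1, 1), "roc")
#' @export
aucScore <- function(probs, labels, curve = c("roc", "pr")) {
  curve <- match.arg(curve)
  labels <- as.integer(labels)
  stopifnot(length(probs) == length(labels))
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to compute an AUC")
  if (curve == "roc") {
    r <- rank(probs, ties.method = "average")
    return((sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg))
  }
  # PR: descending threshold sweep over distinct scores
  ord <- order(probs, decreasing = TRUE)
  y <- labels[ord]
  p <- probs[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(p[-1] != p[-length(p)], TRUE)   # last index of each tie group
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  dr <- diff(c(0, rec))
  sum(prec * dr)
}

#' Early-seizure label variant
#'
#' Re-labels windows for the early-detection metric: windows starting within
#' the first `horizon` seconds of a seizure onset are positive; later
#' in-seizure windows are excluded (NA), since a detection there is neither
#' an early success nor a false alarm; interictal windows stay negative.
#'
#' @param starts window start times (s).
#' @param annotations seizure annotation data.frame.
#' @param horizon early-detection horizon in seconds (10).
#' @return integer vector of 1/0/NA labels.
#' @export
earlyLabels <- function(starts, annotations, horizon = 10) {
  full <- windowLabels(starts, annotations)
  early <- integer(length(starts))
  for (i in seq_len(nrow(annotations))) {
    on <- annotations$onset[i]
    early[starts >= on & starts < min(on + horizon, annotations$offset[i])] <- 1L
  }
  out <- ifelse(full == 1L & early == 0L, NA_integer_, early)
  out
}

#' Threshold a probability series into detection events
#'
#' One event per second whose probability meets the threshold; each event is
#' flagged as inside or outside the annotated seizures.
#'
#' @param probs per-second probability series.
#' @param starts window start times (s); defaults to `0, 1, 2, ...`.
#' @param threshold detection threshold in `[0, 1]`.
#' @param annotations seizure annotation data.frame (may be empty).
#' @return data.frame of events: `time`, `insideSeizure`.
#' @export
thresholdDetections <- function(probs, threshold, starts = NULL,
                                annotations = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.null(starts)) starts <- seq_along(probs) - 1
  hit <- probs >= threshold
  data.frame(time = starts[hit],
             insideSeizure = windowLabels(starts[hit], annotations) == 1L)
}

#' Event-level detection metrics
#'
#' Sensitivity (fraction of seizures with at least one in-seizure event),
#' false detection rate per hour with 5 s deduplication (after a counted
#' false event, all false events within the following `dedupWindow` seconds
#' are suppressed, greedily from the earliest), and the mean detection delay
#' over detected seizures (first in-seizure event time minus onset).
#'
#' @param events data.frame from [thresholdDetections()].
#' @param annotations seizure annotation data.frame.
#' @param recordHours record duration in hours (> 0).
#' @param dedupWindow deduplication window in seconds (5).
#' @return list: `sensitivity`, `fdrPerHour`, `meanDelay` (NA if no seizure
#'   detected), `falseEvents` (counted, post-deduplication).
#' @examples
#' ev <- data.frame(time = c(100, 102, 104, 110), insideSeizure = FALSE)
#' eventMetrics(ev, seizureAnnotations(1000, 1010), 1)$falseEvents  # 2
#' @export
eventMetrics <- function(events, annotations, recordHours, dedupWindow = 5) {
  if (recordHours <= 0) stop("recordHours must be positive")
  falseTimes <- sort(events$time[!events$insideSeizure])
  counted <- numeric(0)
  suppressUntil <- -Inf
  for (tt in falseTimes) {
    if (tt > suppressUntil) {
      counted <- c(counted, tt)
      suppressUntil <- tt + dedupWindow
    }
  }
  nSz <- nrow(annotations)
  detected <- logical(nSz)
  delays <- rep(NA_real_, nSz)
  if (nSz > 0) {
    for (i in seq_len(nSz)) {
      inSz <- events$time[events$insideSeizure &
                            events$time >= annotations$onset[i] &
                            events$time < annotations$offset[i]]
      if (length(inSz)) {
        detected[i] <- TRUE
        delays[i] <- min(inSz) - annotations$onset[i]
      }
    }
  }
  list(sensitivity = if (nSz) mean(detected) else NA_real_,
       fdrPerHour = length(counted) / recordHours,
       meanDelay = if (any(detected)) mean(delays[detected]) else NA_real_,
       falseEvents = length(counted))
}

#' F1-optimal probability threshold
#'
#' Scans the finite set of observed probability values and returns the
#' threshold maximizing the window-level F1 score, breaking ties toward the
#' higher threshold.
#'
#' @param probs probability series.
#' @param labels 0/1 window labels (both classes present).
#' @return list: `threshold`, `f1`.
#' @examples
#' f1OptimalThreshold(c(.1, .2, .6, .7, .8, .9), c(0, 0, 0, 1, 1, 1))
#' @export
f1OptimalThreshold <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to optimize F1")
  cand <- sort(unique(probs), decreasing = TRUE)
  best <- -Inf
  bestTheta <- cand[1]
  for (th in cand) {                   # descending: ties keep the higher
    pred <- probs >= th
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best) {
      best <- f1
      bestTheta <- th
    }
  }
  list(threshold = bestTheta, f1 = best)
}

#' Leave-one-seizure-out cross-validation
#'
#' The evaluation protocol: for each annotated seizure, hold out its
#' surrounding segment for testing, train the detector on all remaining
#' data, and compute per-second probabilities on the held-out segment. The
#' RNN additionally reserves one training seizure's segment as its
#' early-stopping validation set. Per-fold window metrics (AUCs, early
#' variants) and event metrics at the F1-optimal threshold are aggregated to
#' patient level as the mean over folds.
#'
#' @param recording a preprocessed (re-referenced) [EegRecording-class].
#' @param annotations seizure annotation data.frame (>= 2 seizures).
#' @param detector `"rf"`, `"cnn"` or `"rnn"`.
#' @param config a [trainConfig()].
#' @param cnnEpochs epoch budget for the CNN path.
#' @param segmentPad seconds of context kept around each held-out seizure
#'   (the "test segment"); training excludes the whole segment.
#' @return list with `folds` (per-fold data.frame), `summary` (mean and
#'   median over folds), `probs` (per-fold probability series).
#' @export
leaveOneSeizureOut <- function(recording, annotations,
                               detector = c("rf", "cnn", "rnn"),
                               config = trainConfig(),
                               cnnEpochs = 50, segmentPad = 8) {
  detector <- match.arg(detector)
  nSz <- nrow(annotations)
  if (nSz < 2) stop("leave-one-seizure-out needs at least 2 seizures")
  fs <- recording@samplingRate
  n <- nrow(recording@samples)
  dur <- n / fs
  segBounds <- function(i) {
    c(max(0, annotations$onset[i] - segmentPad),
      min(dur, annotations$offset[i] + segmentPad))
  }
  slice <- function(lo, hi) {
    idx <- (floor(lo * fs) + 1L):min(n, floor(hi * fs))
    eegRecording(recording@samples[idx, , drop = FALSE], fs,
                 channelNames = recording@channelNames,
                 validMask = recording@validMask[idx],
                 referenced = recording@referenced)
  }
  shiftAnn <- function(ann, lo, hi) {
    keep <- ann$offset > lo & ann$onset < hi
    out <- ann[keep, , drop = FALSE]
    out$onset <- pmax(out$onset - lo, 0)
    out$offset <- pmin(out$offset, hi) - lo
    out
  }
  rows <- list()
  probsList <- list()
  for (k in seq_len(nSz)) {
    tb <- segBounds(k)
    # training recording: everything outside the held-out segment, masked
    trainRec <- recording
    maskIdx <- (floor(tb[1] * fs) + 1L):min(n, floor(tb[2] * fs))
    trainRec@validMask[maskIdx] <- FALSE
    valSz <- if (detector == "rnn") (k %% nSz) + 1L else NA_integer_
    if (!is.na(valSz)) {
      vb <- segBounds(valSz)
      vIdx <- (floor(vb[1] * fs) + 1L):min(n, floor(vb[2] * fs))
      trainRec@validMask[vIdx] <- FALSE
    }
    testRec <- slice(tb[1], tb[2])
    testAnn <- shiftAnn(annotations, tb[1], tb[2])
    foldSeed <- .substream(config$rngSeed, 991 * k)
    foldCfg <- config
    foldCfg$rngSeed <- foldSeed

    if (detector == "rf") {
      fm <- featureMatrix(trainRec, annotations)
      model <- trainRf(fm[, -(1:2)], fm$ictal, rngSeed = foldSeed)
      testWin <- makeTrainingWindows(testRec, testAnn, "test", foldCfg)
      probs <- predictProba(model, testWin$windows, fs)
    } else {
      tw <- makeTrainingWindows(trainRec, annotations, "train", foldCfg)
      testWin <- makeTrainingWindows(testRec, testAnn, "test", foldCfg)
      C <- ncol(recording@samples)
      if (detector == "cnn") {
        model <- buildCnn(C, rngSeed = foldSeed)
        model <- trainNn(model, tw$windows, tw$labels, foldCfg,
                         epochs = cnnEpochs)
      } else {
        vrec <- slice(segBounds(valSz)[1], segBounds(valSz)[2])
        vann <- shiftAnn(annotations, segBounds(valSz)[1], segBounds(valSz)[2])
        vw <- makeTrainingWindows(vrec, vann, "validation", foldCfg)
        model <- buildRnn(C, rngSeed = foldSeed)
        model <- trainNn(model, tw$windows, tw$labels, foldCfg,
                         validation = list(windows = vw$windows,
                                           labels = vw$labels))
      }
      probs <- predictProba(model, testWin$windows, fs)
      if (detector == "rnn") probs <- smoothProbs(probs)
    }
    labs <- testWin$labels
    starts <- testWin$starts
    eLab <- earlyLabels(starts, testAnn)
    keep <- !is.na(eLab)
    th <- f1OptimalThreshold(probs, labs)
    ev <- thresholdDetections(probs, th$threshold, starts, testAnn)
    em <- eventMetrics(ev, testAnn, recordHours = diff(tb) / 3600)
    rows[[k]] <- data.frame(
      fold = k,
      aucRoc = aucScore(probs, labs, "roc"),
      aucPr = aucScore(probs, labs, "pr"),
      earlyAucRoc = if (sum(eLab[keep] == 1) && sum(eLab[keep] == 0))
        aucScore(probs[keep], eLab[keep], "roc") else NA_real_,
      earlyAucPr = if (sum(eLab[keep] == 1) && sum(eLab[keep] == 0))
        aucScore(probs[keep], eLab[keep], "pr") else NA_real_,
      sensitivity = em$sensitivity,
      fdrPerHour = em$fdrPerHour,
      meanDelay = em$meanDelay,
      threshold = th$threshold)
    probsList[[k]] <- data.frame(start = starts, prob = probs, label = labs)
  }
  folds <- do.call(rbind, rows)
  metricCols <- setdiff(names(folds), "fold")
  summ <- data.frame(
    metric = metricCols,
    mean = vapply(metricCols, function(mc) mean(folds[[mc]], na.rm = TRUE),
                  numeric(1)),
    median = vapply(metricCols, function(mc)
      stats::median(folds[[mc]], na.rm = TRUE), numeric(1)))
  rownames(summ) <- NULL
  list(folds = folds, summary = summ, probs = probsList)
}
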