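#' Training configuration for the neural detectors
#'
#' Collects the fixed training hyperparameters: for the CNN 500 epochs at
#' batch size 512 with Adam at learning rate 1e-3 and class-weighted binary
#' cross-entropy; for the RNN mini-batches of 256 with Adam, binary
#' cross-entropy, and early stopping with patience 10 on the validation loss.
#' Moving-window strides: 16 samples for interictal windows and 1 for ictal
#' windows during training/validation, 256 (non-overlapping, 1 Hz) at test
#' time.
#'
#' @param cnnEpochs,cnnBatch,cnnLr CNN schedule (defaults 500 / 512 / 1e-3).
#' @param rnnBatch,rnnMaxEpochs,rnnPatience RNN schedule (256 / 100 / 10).
#' @param strideInterictal,strideIctal,strideTest window strides in samples.
#' @param rngSeed integer seed governing shuffling, dropout and weight
#'   initialization.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(cnnEpochs = 500, cnnBatch = 512, cnnLr = 1e-3,
                        rnnBatch = 256, rnnMaxEpochs = 100, rnnPatience = 10,
                        strideInterictal = 16, strideIctal = 1,
                        strideTest = 256, rngSeed = 1L) {
  stopifnot(strideInterictal >= 1, strideIctal >= 1, strideTest >= 1)
  structure(list(cnnEpochs = cnnEpochs, cnnBatch = cnnBatch, cnnLr = cnnLr,
                 rnnBatch = rnnBatch, rnnMaxEpochs = rnnMaxEpochs,
                 rnnPatience = rnnPatience,
                 strideInterictal = strideInterictal,
                 strideIctal = strideIctal, strideTest = strideTest,
                 rngSeed = as.integer(rngSeed)), class = "TrainConfig")
}

#' Cut a recording into labelled windows
#'
#' Slides a 1 s (256-sample) window over the signal. For the `train` and
#' `validation` roles the stride is 16 samples in interictal stretches and 1
#' sample inside seizures (oversampling the rare class); for `test` the
#' stride is 256 samples, one window per second. A window is labelled ictal
#' iff its start time lies inside `[onset, offset)` of a seizure; windows
#' overlapping invalid samples are skipped.
#'
#' @param recording a preprocessed [EegRecording-class].
#' @param annotations seizure annotation data.frame.
#' @param role `"train"`, `"validation"` or `"test"`.
#' @param config a [trainConfig()].
#' @return list with `windows` (array N x 256 x C), `labels` (0/1 integer),
#'   `starts` (window start times, s).
#' @export
makeTrainingWindows <- function(recording, annotations,
                                role = c("train", "validation", "test"),
                                config = trainConfig()) {
  role <- match.arg(role)
  fs <- recording@samplingRate
  nw <- round(fs)
  n <- nrow(recording@samples)
  if (n <= nw) stop("signal must be longer than one window")
  if (role == "test") {
    starts <- seq(1L, n - nw + 1L, by = config$strideTest)
  } else {
    all1 <- seq(1L, n - nw + 1L, by = 1L)
    tall <- (all1 - 1) / fs
    labAll <- windowLabels(tall, annotations)
    ict <- all1[labAll == 1L]
    int <- all1[labAll == 0L]
    pick <- function(v, by) if (length(v)) v[seq(1L, length(v), by = by)]
                            else integer(0)
    starts <- sort(c(pick(ict, config$strideIctal),
                     pick(int, config$strideInterictal)))
  }
  ok <- vapply(starts, function(s)
    all(recording@validMask[s:(s + nw - 1L)]), logical(1))
  starts <- starts[ok]
  C <- ncol(recording@samples)
  win <- array(0, c(length(starts), nw, C))
  for (i in seq_along(starts)) {
    win[i, , ] <- recording@samples[starts[i]:(starts[i] + nw - 1L), ]
  }
  tsec <- (starts - 1) / fs
  list(windows = win, labels = windowLabels(tsec, annotations),
       starts = tsec)
}

#' Train the random-forest detector
#'
#' Fits the fixed-configuration forest on the per-window feature matrix:
#' 100 trees of maximum depth 10, 4 candidate features per split, bootstrap
#' resampling and class weights inversely proportional to the class
#' frequencies. Deterministic under the configured seed.
#'
#' @param features numeric matrix/data.frame of per-window features
#'   (16 x C columns).
#' @param labels 0/1 window labels; both classes must be present.
#' @param nTrees,maxDepth,mtry forest size, depth cap and per-node feature
#'   draw.
#' @param rngSeed integer seed.
#' @return object of class `rfModel` wrapping the fitted forest.
#' @export
trainRf <- function(features, labels, nTrees = 100, maxDepth = 10,
                    mtry = 4, rngSeed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to train the forest")
  df <- as.data.frame(features)
  df$.y <- factor(labels, levels = c(0, 1))
  freq <- table(df$.y)
  cw <- as.numeric(sum(freq) / (2 * freq))      # inverse class frequency
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = nTrees, max.depth = maxDepth, mtry = min(mtry, ncol(features)),
    replace = TRUE, probability = TRUE,
    class.weights = cw, seed = as.integer(rngSeed),
    num.threads = 1)
  structure(list(fit = fit, featureNames = colnames(df)[colnames(df) != ".y"],
                 nTrees = nTrees, maxDepth = maxDepth, mtry = mtry),
            class = "rfModel")
}

#' Train a neural detector
#'
#' Trains a [buildCnn()] or [buildRnn()] model on labelled raw windows.
#' The CNN path normalizes inputs with `tanh(0.2 x / sd)` (the training-set
#' standard deviation is stored on the model), weights the loss by inverse
#' class frequency, and runs a fixed number of epochs; an optional
#' `baseModel` provides a warm start (fine-tuning). The RNN path feeds the
#' (padded, SD-scaled) time derivative, and early-stops on the validation
#' loss of a held-out seizure with the configured patience.
#'
#' @param model an untrained `cnnModel` or `rnnModel`.
#' @param windows array N x 256 x C of raw (preprocessed) samples.
#' @param labels 0/1 window labels.
#' @param config a [trainConfig()].
#' @param validation for the RNN: list with `windows` and `labels` used for
#'   early stopping (required).
#' @param baseModel optional trained model of the same class to warm-start
#'   from.
#' @param epochs override of the epoch budget (defaults to the config's).
#' @return the trained model, with a `trainingLog` element (per-epoch loss,
#'   stop epoch, seed).
#' @export
trainNn <- function(model, windows, labels, config = trainConfig(),
                    validation = NULL, baseModel = NULL, epochs = NULL) {
  labels <- as.numeric(labels)
  isCnn <- inherits(model, "cnnModel")
  if (!isCnn && !inherits(model, "rnnModel"))
    stop("model must come from buildCnn() or buildRnn()")
  if (!is.null(baseModel)) {
    stopifnot(identical(class(baseModel), class(model)))
    model$params <- baseModel$params
    model$sdTrain <- baseModel$sdTrain
    if (isCnn) model$bnState <- baseModel$bnState
  }
  set.seed(.substream(config$rngSeed, 17))
  sdTrain <- if (!is.null(baseModel) && is.finite(model$sdTrain))
    model$sdTrain else stats::sd(as.numeric(windows))
  model$sdTrain <- sdTrain

  if (isCnn) {
    X <- normalizeInput(windows, sdTrain)
    nEpochs <- if (is.null(epochs)) config$cnnEpochs else epochs
    freq <- c(sum(labels == 0), sum(labels == 1))
    cw <- sum(freq) / (2 * pmax(freq, 1))
    w <- ifelse(labels == 1, cw[2], cw[1])
    opt <- .adamInit(model$params)
    log <- numeric(nEpochs)
    for (ep in seq_len(nEpochs)) {
      st <- .runEpoch(model, X, labels, w, config$cnnBatch, opt, config$cnnLr)
      model <- st$model
      opt <- st$opt
      log[ep] <- st$loss
    }
    model$trainingLog <- list(loss = log, epochs = nEpochs,
                              seed = config$rngSeed, sdTrain = sdTrain)
    return(model)
  }

  # RNN path: derivative input, early stopping on validation loss
  if (is.null(validation))
    stop("early stopping requires validation data")
  X <- .rnnInput(windows, sdTrain)
  Xv <- .rnnInput(validation$windows, sdTrain)
  yv <- as.numeric(validation$labels)
  nEpochs <- if (is.null(epochs)) config$rnnMaxEpochs else epochs
  w <- rep(1, length(labels))
  opt <- .adamInit(model$params)
  best <- Inf
  bestParams <- model$params
  bestEpoch <- 0L
  log <- numeric(0)
  vlog <- numeric(0)
  for (ep in seq_len(nEpochs)) {
    st <- .runEpoch(model, X, labels, w, config$rnnBatch, opt, 1e-3)
    model <- st$model
    opt <- st$opt
    vloss <- .nnLoss(model, Xv, yv)
    log <- c(log, st$loss)
    vlog <- c(vlog, vloss)
    if (vloss < best - 1e-6) {
      best <- vloss
      bestParams <- model$params
      bestEpoch <- ep
    } else if (ep - bestEpoch >= config$rnnPatience) {
      break
    }
  }
  model$params <- bestParams
  model$trainingLog <- list(loss = log, valLoss = vlog,
                            bestEpoch = bestEpoch, stopEpoch = length(log),
                            seed = config$rngSeed, sdTrain = sdTrain)
  model
}

# derivative + padding + SD conditioning, vectorized over the window array
.rnnInput <- function(windows, sdTrain) {
  d <- dim(windows)
  out <- windows
  out[, 2:d[2], ] <- windows[, 2:d[2], , drop = FALSE] -
    windows[, 1:(d[2] - 1), , drop = FALSE]
  out[, 1, ] <- out[, 2, ]              # repeat first difference
  out / sdTrain
}

#' Per-second seizure probabilities
#'
#' Runs a trained detector over test windows (one per second). The CNN path
#' applies the inference normalization (`lintanh` in place of `tanh`, unless
#' `linear = FALSE`); the RNN path applies the time-derivative input
#' transform; the RF path extracts the 16-per-channel feature vector.
#'
#' @param model an `rfModel`, `cnnModel` or `rnnModel`.
#' @param windows array N x 256 x C of raw (preprocessed) window samples.
#' @param samplingRate sampling rate in Hz (used by the RF feature path).
#' @param linear CNN only: use the piecewise-linear tanh approximation
#'   (default TRUE, the embedded inference path).
#' @return numeric vector of probabilities in `[0, 1]`, one per window.
#' @export
predictProba <- function(model, windows, samplingRate = 256, linear = TRUE) {
  d <- dim(windows)
  if (inherits(model, "rfModel")) {
    feats <- t(apply(windows, 1, function(w)
      extractFeatures(matrix(w, d[2], d[3]), samplingRate)))
    colnames(feats) <- model$featureNames
    pr <- stats::predict(model$fit, data = as.data.frame(feats),
                         num.threads = 1)$predictions
    return(as.numeric(pr[, "1"]))
  }
  if (inherits(model, "cnnModel")) {
    if (d[3] != model$C) stop("wrong channel count for this model")
    X <- normalizeInput(windows, model$sdTrain, linear = linear)
    return(.sigmoid(.nnLogits(model, X)))
  }
  if (inherits(model, "rnnModel")) {
    if (d[3] != model$C) stop("wrong channel count for this model")
    X <- .rnnInput(windows, model$sdTrain)
    return(.sigmoid(.nnLogits(model, X)))
  }
  stop("unknown model type")
}

#' Moving-median smoothing of a probability series
#'
#' Moving median of width 3, the post-processing used on the per-second
#' probability stream; edges use the shrinking window (so length-1 and
#' length-2 series pass through unchanged).
#'
#' @param p numeric probability series.
#' @return smoothed series, same length.
#' @examples
#' smoothProbs(c(0, 1, 0))  # middle value becomes 0
#' @export
smoothProbs <- function(p) {
  n <- length(p)
  if (n < 3) return(p)
  out <- p
  out[2:(n - 1)] <- vapply(2:(n - 1), function(i)
    stats::median(p[(i - 1):(i + 1)]), numeric(1))
  out
}
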