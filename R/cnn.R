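#' Input normalization for the convolutional detector
#'
#' Rescales a raw window by the training-set standard deviation and squashes
#' it with `tanh(0.2 * x / sd)`, bounding the input to (-1, 1) while keeping
#' typical EEG amplitudes in the near-linear region. At inference the
#' hardware-friendly piecewise-linear [lintanh()] replaces the hyperbolic
#' tangent.
#'
#' @param x numeric vector/matrix/array of raw samples (uV).
#' @param sdTrain standard deviation of the training data (uV), > 0.
#' @param linear use [lintanh()] instead of `tanh` (inference path).
#' @return normalized values, same shape as `x`.
#' @examples
#' normalizeInput(5, 1)          # tanh(1) = 0.7616
#' normalizeInput(5, 1, TRUE)    # lintanh(1) = 0.8333
#' @export
normalizeInput <- function(x, sdTrain, linear = FALSE) {
  if (length(sdTrain) != 1 || !is.finite(sdTrain) || sdTrain <= 0)
    stop("sdTrain must be a single positive number")
  z <- 0.2 * x / sdTrain
  if (linear) lintanh(z) else tanh(z)
}

#' Piecewise-linear approximation of the hyperbolic tangent
#'
#' `x / 1.2` for `|x| <= 1.2`, saturating at +/-1 beyond; avoids a lookup
#' table on embedded targets. Deviates from `tanh` by at most ~0.168.
#'
#' @param x numeric.
#' @return numeric, same shape.
#' @examples
#' lintanh(c(-3, 0, 0.6, 2))  # -1, 0, 0.5, 1
#' @export
lintanh <- function(x) {
  pmin(pmax(x / 1.2, -1), 1)
}

#' Build the convolutional seizure detector
#'
#' Instantiates the fixed CNN: three valid (unpadded) convolution blocks with
#' batch normalization, ReLU and 1x4 max pooling / dropout, followed by two
#' dense layers and a sigmoid output, for a `C x 256` raw-EEG window. Returns
#' the untrained model together with a per-layer report of output shapes and
#' parameter counts, which downstream energy counting shares.
#'
#' @param C number of input channels (4 for the default montage).
#' @param inputLength samples per window (256 for 1 s at 256 Hz).
#' @param rngSeed seed for weight initialization.
#' @return object of class `cnnModel` with elements `params`, `layerReport`
#'   (data.frame: layer, operation, output, parameters), `C`, `inputLength`,
#'   and `sdTrain` (filled in by training).
#' @examples
#' m <- buildCnn(4)
#' m$layerReport
#' sum(m$layerReport$parameters)  # 5614
#' @export
buildCnn <- function(C = 4, inputLength = 256, rngSeed = 1L) {
  stopifnot(C >= 1)
  set.seed(as.integer(rngSeed))
  conv <- list(
    list(filters = 15, kernel = 25, maps = C),
    list(filters = 15, kernel = 11, maps = 15),
    list(filters = 10, kernel = 5, maps = 15)
  )
  pools <- c(4, 4, NA)
  params <- list()
  report <- list()
  tlen <- inputLength
  report[[1]] <- data.frame(layer = "", operation = sprintf("Input (%dx%d)", C, inputLength),
                            output = sprintf("%dx%dx1", C, inputLength), parameters = 0)
  for (i in seq_along(conv)) {
    cv <- conv[[i]]
    tlen <- tlen - cv$kernel + 1L
    if (tlen < 1L)
      stop(sprintf("conv layer %d: input too short for kernel %d", i, cv$kernel))
    nin <- cv$kernel * cv$maps
    params[[paste0("W", i)]] <- matrix(.glorot(nin, cv$filters), nin, cv$filters)
    params[[paste0("b", i)]] <- numeric(cv$filters)
    params[[paste0("gamma", i)]] <- rep(1, cv$filters)
    params[[paste0("beta", i)]] <- numeric(cv$filters)
    report[[length(report) + 1]] <- data.frame(
      layer = as.character(length(report)),
      operation = sprintf("%d x Conv2D (%s)", cv$filters,
                          if (i == 1) sprintf("%dx%d", C, cv$kernel)
                          else sprintf("1x%d", cv$kernel)),
      output = sprintf("1x%dx%d", tlen, cv$filters),
      parameters = nin * cv$filters + cv$filters)
    report[[length(report) + 1]] <- data.frame(
      layer = "", operation = "Batch Normalization",
      output = sprintf("1x%dx%d", tlen, cv$filters),
      parameters = 4L * cv$filters)
    if (!is.na(pools[i])) {
      tlen <- tlen %/% pools[i]
      report[[length(report) + 1]] <- data.frame(
        layer = as.character(length(report) - 1),
        operation = sprintf("MaxPool2D (1x%d)", pools[i]),
        output = sprintf("1x%dx%d", tlen, cv$filters), parameters = 0)
    }
    report[[length(report) + 1]] <- data.frame(
      layer = "", operation = "Dropout (0.2)",
      output = sprintf("1x%dx%d", tlen, cv$filters), parameters = 0)
  }
  flat <- tlen * conv[[3]]$filters
  dense <- c(8, 4, 1)
  nin <- flat
  for (i in seq_along(dense)) {
    params[[paste0("Wd", i)]] <- matrix(.glorot(nin, dense[i]), nin, dense[i])
    params[[paste0("bd", i)]] <- numeric(dense[i])
    report[[length(report) + 1]] <- data.frame(
      layer = as.character(5 + i),
      operation = if (i < 3) sprintf("Dense (%d)", dense[i]) else "Sigmoid",
      output = as.character(dense[i]), parameters = nin * dense[i] + dense[i])
    nin <- dense[i]
  }
  bnState <- lapply(conv, function(cv)
    list(rmean = numeric(cv$filters), rvar = rep(1, cv$filters)))
  structure(list(params = params, bnState = bnState,
                 layerReport = do.call(rbind, report),
                 C = C, inputLength = inputLength,
                 conv = conv, pools = pools, dropout = 0.2,
                 sdTrain = NA_real_),
            class = "cnnModel")
}

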