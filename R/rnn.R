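#' Discrete time derivative of a multichannel window
#'
#' First difference along the time axis for every channel,
#' `dx[c, k] = x[c, k] - x[c, k-1]`. Used as the input representation of the
#' recurrent detector. With `pad = TRUE` the first difference is repeated so
#' the window keeps its original length (the architecture expects 256 steps).
#'
#' @param x numeric matrix, time x channels (or a vector for one channel).
#' @param pad repeat the first difference to preserve length.
#' @return matrix of differences, time x channels.
#' @examples
#' timeDerivative(c(1, 2, 4, 8), pad = FALSE)  # 1 2 4
#' @export
timeDerivative <- function(x, pad = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples to differentiate")
  d <- diff(x)
  if (pad) d <- rbind(d[1, , drop = FALSE], d)
  d
}

#' Build the recurrent (LSTM) seizure detector
#'
#' Instantiates the fixed RNN: one LSTM layer of 20 cells over 256 time steps
#' of C values each, dropout 0.1, a time-distributed linear dense layer of 20
#' units, global average pooling over time, and a 1-unit sigmoid output.
#' Returns the untrained model and a per-layer parameter report.
#'
#' @param C input values per time step (4 for the default montage).
#' @param nCells LSTM cells (20).
#' @param steps time steps per window (256).
#' @param rngSeed seed for weight initialization.
#' @return object of class `rnnModel` with `params`, `layerReport`, `C`,
#'   `steps`, `nCells` and `sdTrain` (filled in by training).
#' @examples
#' m <- buildRnn(4)
#' m$layerReport
#' @export
buildRnn <- function(C = 4, nCells = 20, steps = 256, rngSeed = 1L) {
  stopifnot(C >= 1, nCells >= 1, steps >= 2)
  set.seed(as.integer(rngSeed))
  nin <- C + nCells
  W <- matrix(.glorot(nin, 4 * nCells), nin, 4 * nCells)
  b <- numeric(4 * nCells)
  b[nCells + seq_len(nCells)] <- 1          # forget-gate bias at 1
  params <- list(
    W = W, b = b,
    V = matrix(.glorot(nCells, nCells), nCells, nCells),
    c0 = numeric(nCells),
    wout = matrix(.glorot(nCells, 1), nCells, 1),
    bout = 0
  )
  report <- data.frame(
    layer = c("", "1", "", "2", "3", "4"),
    operation = c(sprintf("Input (%dx%d)", C, steps),
                  sprintf("LSTM (%d)", nCells), "Dropout (0.1)",
                  sprintf("Time-Distributed Dense (%d)", nCells),
                  "Global Average Pooling 1D", "Dense (1)"),
    output = c(sprintf("%dx%dx1", C, steps),
               sprintf("%dx%d", steps, nCells), sprintf("%dx%d", steps, nCells),
               sprintf("%dx%d", steps, nCells), sprintf("%d", nCells), "1"),
    parameters = c(0, 4 * ((C + nCells) * nCells + nCells), 0,
                   nCells * nCells + nCells, 0, nCells + 1))
  structure(list(params = params, layerReport = report, C = C,
                 steps = steps, nCells = nCells, dropout = 0.1,
                 sdTrain = NA_real_),
            class = "rnnModel")
}
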