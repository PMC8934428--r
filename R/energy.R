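# Platform-independent energy model: count arithmetic operations (AOs) and
# memory accesses (MAs) per classification and convert them to energy with
# the per-operation cost table.
#
# Counting conventions (central rule set; see the methods vignette):
#  * A fused multiply-accumulate ("mac") is ONE arithmetic operation and is
#    costed as one float add plus one float multiply (4.6 pJ).
#  * Each scalar operand fetched from a working array costs 1 load; each
#    scalar result written back costs 1 store. Register-resident loop
#    accumulators and counters are free.
#  * Convolution/dense MACs: operand + weight fetched per MAC (no reuse
#    modelled). LSTM recurrent state (h, c) is register-resident within a
#    time step: only the input values are re-fetched per MAC, weights per
#    MAC as elsewhere.
#  * Division by a constant counts as a float multiply; division by a
#    runtime value and square root cost a float divide.
#  * abs and ReLU cost one compare; log2 costs one generic 1-cycle float op
#    plus one LUT load; sigmoid/tanh activations are LUT lookups (1 load
#    plus one 1-cycle op for the index computation).

#' Total energy of an operation ledger
#'
#' `E_tot = (N_load + N_store) * E_m + sum_x N_x * E_x`, with the fused MAC
#' costed as one float add plus one float multiply.
#'
#' @param ledger an [OpLedger-class] or [EnergyReport-class].
#' @param costs cost table from [operationCosts()] (pJ).
#' @return energy in pJ.
#' @examples
#' totalEnergy(opLedger("x", load = 2, store = 1, float_add = 1))  # 15.9
#' @export
totalEnergy <- function(ledger, costs = operationCosts()) {
  if (is(ledger, "EnergyReport")) {
    return(sum(vapply(ledger@ledgers, totalEnergy, numeric(1),
                      costs = ledger@costs)))
  }
  ct <- ledger@counts
  (ct[["load"]] + ct[["store"]]) * costs[["memory"]] +
    ct[["mac"]] * (costs[["float_add"]] + costs[["float_mult"]]) +
    ct[["float_add"]] * costs[["float_add"]] +
    ct[["float_mult"]] * costs[["float_mult"]] +
    ct[["float_div"]] * costs[["float_div"]] +
    ct[["int_add"]] * costs[["int_add"]] +
    ct[["int_mult"]] * costs[["int_mult"]] +
    ct[["compare"]] * costs[["compare"]] +
    ct[["onecycle"]] * costs[["onecycle"]]
}

#' Arithmetic-operation count of a ledger or report
#'
#' Sum over all arithmetic classes; a fused MAC counts once.
#' @param ledger an [OpLedger-class] or [EnergyReport-class].
#' @return count of arithmetic operations.
#' @export
aoCount <- function(ledger) {
  if (is(ledger, "EnergyReport"))
    return(sum(vapply(ledger@ledgers, aoCount, numeric(1))))
  sum(ledger@counts[setdiff(.opClasses, c("load", "store"))])
}

#' Memory-access count of a ledger or report
#' @param ledger an [OpLedger-class] or [EnergyReport-class].
#' @return count of loads plus stores.
#' @export
maCount <- function(ledger) {
  if (is(ledger, "EnergyReport"))
    return(sum(vapply(ledger@ledgers, maCount, numeric(1))))
  sum(ledger@counts[c("load", "store")])
}

#' Multiply-accumulate count
#'
#' Sums the MAC-class operations over selected components of a report.
#'
#' @param report an [EnergyReport-class].
#' @param components character vector of component labels (regular-expression
#'   match), or NULL for all.
#' @return MAC count (integer-valued).
#' @examples
#' rep <- cnnOpCounts()
#' macCount(rep, "conv")  # the three convolutional layers
#' @export
macCount <- function(report, components = NULL) {
  stopifnot(is(report, "EnergyReport"))
  led <- report@ledgers
  if (!is.null(components)) {
    keep <- vapply(led, function(l)
      any(vapply(components, grepl, logical(1), x = l@component)), logical(1))
    led <- led[keep]
  }
  sum(vapply(led, function(l) l@counts[["mac"]], numeric(1)))
}

# ---- feature op counting -------------------------------------------------

#' Operation counts of one feature (single channel)
#'
#' Ledger of one feature computed on a single channel of an `N_w`-sample
#' window, under the package's counting conventions. Shared intermediates
#' are their own components (`zero_mean` includes the mean, `squares` the
#' squared centered samples, `power_spectrum` the Hann window, a radix-2
#' real FFT and the bin squaring); they are counted once per channel and
#' amortized across the features that consume them.
#'
#' @param feature one of [featureNames()], or `"zero_mean"`, `"squares"`,
#'   `"power_spectrum"`.
#' @param Nw samples per window (256).
#' @param entropyBins amplitude-entropy histogram bins (16).
#' @return an [OpLedger-class].
#' @export
featureOpCounts <- function(feature, Nw = 256, entropyBins = 16) {
  L <- Nw %/% 2 + 1
  led <- function(...) opLedger(feature, ...)
  switch(feature,
    zero_mean =                       # x - mean (mean held in a register)
      led(load = Nw, float_add = Nw, store = Nw),
    squares =                         # centered^2, stored
      led(load = Nw, float_mult = Nw, store = Nw),
    power_spectrum = {
      nb <- (Nw / 2) * log2(Nw)       # radix-2 butterflies
      led(
        # Hann: coefficient + sample loads, one multiply, store
        load = 2 * Nw +
          # FFT: two complex operands + complex twiddle per butterfly
          6 * nb +
          # squaring: re/im per bin
          2 * L,
        store = Nw + 4 * nb + L,
        float_mult = Nw + 4 * nb + 2 * L,
        float_add = 6 * nb + L)
    },
    maximum = led(load = Nw, compare = Nw - 1, store = 1),
    mean = led(load = Nw, float_add = Nw - 1, float_mult = 1, store = 1),
    mad = led(load = Nw, compare = Nw, float_add = Nw - 1, float_mult = 1,
              store = 1),
    variance = led(load = Nw, float_add = Nw - 1, float_mult = 1, store = 1),
    skewness =                        # centered * squares, s = sqrt(var)
      led(load = 2 * Nw, float_mult = Nw + 3, float_add = Nw - 1,
          float_div = 2, store = 1),
    kurtosis =                        # squares^2, normalize by var^2
      led(load = Nw, float_mult = Nw + 2, float_add = Nw - 1, float_div = 1,
          store = 1),
    line_length =                     # |x_k - x_{k-1}|, accumulated
      led(load = 2 * (Nw - 1), float_add = (Nw - 1) + (Nw - 2),
          compare = Nw - 1, store = 1),
    entropy = {
      nb <- entropyBins
      led(
        # min scan; per-sample bin update (load sample, histogram
        # read-modify-write); probabilities; p*log2(p) with LUT log
        load = Nw + Nw + Nw + nb + 2 * nb + nb,
        store = 1 + Nw + nb + 1,
        compare = Nw - 1,
        float_add = 1 + Nw + (nb - 1),
        float_mult = Nw + nb + nb + 1,
        float_div = 1,
        onecycle = Nw + nb,           # floor per sample, log2 per bin
        int_add = Nw)
    },
    spectral_entropy =
      led(load = L + L + 2 * L,
          store = 1 + L + 1,
          float_add = (L - 1) + (L - 1),
          float_mult = L + L + 1,
          float_div = 1,
          onecycle = L),
    mean_power = led(load = L, float_add = L - 1, float_mult = 1, store = 1),
    max_power = led(load = L, compare = L - 1, store = 1),
    power_variance =
      led(load = L, float_add = L + (L - 1), float_mult = L + 1, store = 1),
    theta_power = .bandLedger(feature, c(4, 8)),
    beta_power = .bandLedger(feature, c(13, 30)),
    gamma_power = .bandLedger(feature, c(30, 45)),
    alpha_power = .bandLedger(feature, c(8, 13)),
    epi_index = led(load = 4, float_add = 2, float_div = 1, store = 1),
    stop("unknown feature: ", feature)
  )
}

.bandLedger <- function(name, band, df = 1) {
  nbins <- floor(band[2] / df) - ceiling(band[1] / df) + 1
  opLedger(name, load = nbins, float_add = nbins - 1, store = 1)
}

#' Energy report of the random-forest detector
#'
#' Builds the complete per-classification ledger of the RF path: the 16
#' features (plus shared intermediates) per channel, scaled by the channel
#' count, and the worst-case classifier stage in which all `nTrees` trees are
#' traversed to full depth (each node evaluation: feature load, threshold
#' load, one compare) followed by vote aggregation.
#'
#' @param C channels (4).
#' @param Nw samples per window (256).
#' @param nTrees,maxDepth forest shape (100, 10).
#' @param costs cost table from [operationCosts()].
#' @return an [EnergyReport-class] with one component per feature and one
#'   for the tree traversal.
#' @examples
#' rep <- rfOpCounts()
#' totalEnergy(rep) / 1e6  # uJ per classification
#' @export
rfOpCounts <- function(C = 4, Nw = 256, nTrees = 100, maxDepth = 10,
                       costs = operationCosts()) {
  comps <- c("zero_mean", "squares", "power_spectrum",
             featureNames(), "alpha_power")
  ledgers <- lapply(comps, function(f)
    scaleLedger(featureOpCounts(f, Nw), C))
  nodes <- nTrees * maxDepth
  trees <- opLedger("tree_traversal",
    load = 2 * nodes + nTrees,        # feature + threshold per node; votes
    compare = nodes + 1,              # node tests + final majority compare
    int_add = nTrees,                 # vote accumulation
    store = 1)
  new("EnergyReport", detector = "rf", ledgers = c(ledgers, list(trees)),
      costs = costs)
}

#' Energy report of the convolutional detector
#'
#' Per-layer ledgers for the fixed CNN at inference: input normalization
#' (divide by the stored SD, piecewise-linear tanh), convolution MACs (one
#' per kernel weight per output position; batch normalization folded into
#' the filter parameters, so free at inference), bias adds, ReLU compares,
#' 4-way max-pool compares, dense-layer MACs and the sigmoid LUT. Dropout is
#' inactive at inference.
#'
#' @param C input channels (4).
#' @param inputLength samples per window (256).
#' @param costs cost table.
#' @return an [EnergyReport-class], one component per layer.
#' @examples
#' rep <- cnnOpCounts()
#' macCount(rep, "conv") # 472800 for C = 4
#' @export
cnnOpCounts <- function(C = 4, inputLength = 256, costs = operationCosts()) {
  conv <- list(
    list(name = "conv1", filters = 15, kernel = 25, maps = C, pool = 4),
    list(name = "conv2", filters = 15, kernel = 11, maps = 15, pool = 4),
    list(name = "conv3", filters = 10, kernel = 5, maps = 15, pool = NA)
  )
  nIn <- C * inputLength
  ledgers <- list(
    # x / sd (multiply by reciprocal) then lintanh: 2 compares + 1 multiply
    opLedger("normalization",
             load = nIn, store = nIn, float_mult = 2 * nIn,
             float_div = 1, compare = 2 * nIn))
  tlen <- inputLength
  for (cv in conv) {
    tlen <- tlen - cv$kernel + 1
    if (tlen < 1)
      stop(sprintf("%s: input too short for kernel %d", cv$name, cv$kernel))
    macs <- tlen * cv$filters * (cv$kernel * cv$maps)
    outs <- tlen * cv$filters
    ledgers[[length(ledgers) + 1]] <- opLedger(cv$name,
      mac = macs, load = 2 * macs + outs,  # operand+weight per MAC, bias
      float_add = outs,                    # bias add (BN folded)
      compare = outs,                      # ReLU
      store = outs)
    if (!is.na(cv$pool)) {
      pout <- (tlen %/% cv$pool) * cv$filters
      ledgers[[length(ledgers) + 1]] <- opLedger(paste0("pool", cv$name),
        load = tlen * cv$filters, compare = 3 * pout, store = pout)
      tlen <- tlen %/% cv$pool
    }
  }
  dense <- list(c(tlen * 10, 8), c(8, 4), c(4, 1))
  for (i in seq_along(dense)) {
    nin <- dense[[i]][1]; nout <- dense[[i]][2]
    macs <- nin * nout
    ledgers[[length(ledgers) + 1]] <- opLedger(paste0("dense", i),
      mac = macs, load = 2 * macs + nout + (if (i == 3) 1 else 0),
      float_add = nout, store = nout,
      compare = if (i < 3) nout else 0)   # ReLU; sigmoid is a LUT load
  }
  new("EnergyReport", detector = "cnn", ledgers = ledgers, costs = costs)
}

#' Energy report of the recurrent detector
#'
#' Per-layer ledgers for the fixed LSTM network at inference: the input time
#' derivative, 256 steps of the standard LSTM recurrence (4 gates of
#' `(C+20) x 20` MACs, bias adds, LUT gate activations, elementwise cell
#' update), the time-distributed dense layer at every step, global average
#' pooling, and the sigmoid output unit. The recurrent state is modelled as
#' register-resident within a step; input values and all weights are fetched
#' per MAC.
#'
#' @param C input values per step (4).
#' @param nCells LSTM cells (20).
#' @param steps time steps (256).
#' @param costs cost table.
#' @return an [EnergyReport-class], one component per layer.
#' @examples
#' rep <- rnnOpCounts()
#' macCount(rep, "lstm")  # 491520 gate MACs for C = 4
#' @export
rnnOpCounts <- function(C = 4, nCells = 20, steps = 256,
                        costs = operationCosts()) {
  H <- nCells
  # input derivative: x_k - x_{k-1} per channel, stored
  deriv <- opLedger("derivative",
    load = 2 * (steps - 1) * C, float_add = (steps - 1) * C,
    store = (steps - 1) * C + C)
  gateMacsX <- 4 * C * H          # input part, operands fetched per MAC
  gateMacsH <- 4 * H * H          # recurrent part, state register-resident
  perStep <- opLedger("lstm",
    mac = gateMacsX + gateMacsH,
    load = (gateMacsX + gateMacsH) +   # weights per MAC
      gateMacsX +                      # input operands per MAC
      H * 4 +                          # recurrent state fetched per gate
      4 * H +                          # biases
      4 * H +                          # gate LUT activations
      H,                               # tanh(c) LUT
    float_add = 4 * H +                # bias adds
      H,                               # c = f*c + i*g accumulate
    float_mult = 3 * H,                # f*c, i*g, o*tanh(c)
    onecycle = 5 * H,                  # LUT index computation per activation
    store = 4 * H +                    # gate outputs
      2 * H)                           # c and h written back
  lstm <- scaleLedger(perStep, steps)
  tdStep <- opLedger("time_distributed_dense",
    mac = H * H,
    load = 2 * H * H + H,             # weights + operands per MAC, biases
    float_add = H, store = H)
  td <- scaleLedger(tdStep, steps)
  pool <- opLedger("global_average_pooling",
    load = H * steps, float_add = H * (steps - 1), float_mult = H,
    store = H)
  outd <- opLedger("dense_output",
    mac = H, load = 2 * H + 1 + 1,    # weights+operands, bias, sigmoid LUT
    float_add = 1, onecycle = 1, store = 1)
  new("EnergyReport", detector = "rnn",
      ledgers = list(deriv, lstm, td, pool, outd), costs = costs)
}

#' Calibrate the energy model against hardware measurements
#'
#' Ordinary least-squares fit `measured = b0 + b1 * estimated`, with the
#' adjusted R-squared and the Pearson correlation between model estimates and
#' measurements. The slope absorbs hardware-dependent per-instruction
#' overhead; the offset absorbs static consumption.
#'
#' @param estimates model-estimated energies (uJ), length >= 3, non-constant.
#' @param measurements measured energies (uJ), same length.
#' @return a [CalibrationFit-class].
#' @examples
#' calibrateHardware(1:5, 2 * (1:5) + 1)  # slope 2, offset 1
#' @export
calibrateHardware <- function(estimates, measurements) {
  stopifnot(length(estimates) == length(measurements), length(estimates) >= 3)
  if (stats::sd(estimates) == 0)
    stop("estimates have zero variance; cannot fit a slope")
  fit <- stats::lm(measurements ~ estimates)
  sm <- summary(fit)
  new("CalibrationFit",
      slope = unname(stats::coef(fit)[2]),
      offset = unname(stats::coef(fit)[1]),
      adjR2 = sm$adj.r.squared,
      pearsonR = stats::cor(estimates, measurements),
      fit = fit)
}
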