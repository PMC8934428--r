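#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Carrier object for all signal-processing stages: a time-by-electrode matrix
#' of samples in microvolts, the sampling rate, electrode labels (one of which
#' may be designated the central electrode of the montage), and a per-sample
#' validity mask used to exclude segments from analysis.
#'
#' @slot samples numeric matrix, time along rows, electrodes along columns (uV).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames character vector of electrode labels (column names).
#' @slot centralChannel label of the centrally positioned electrode, or
#'   `NA_character_` once the recording has been re-referenced.
#' @slot validMask logical vector, one entry per sample (row); `FALSE` marks
#'   samples excluded from windowing.
#' @slot referenced logical; `TRUE` after central re-referencing, in which case
#'   the columns are peripheral-minus-central channels.
#'
#' @seealso [eegRecording()], [generateRecording()], [preprocess()]
#' @export
setClass("EegRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    centralChannel = "character",
    validMask = "logical",
    referenced = "logical"
  )
)

setValidity("EegRecording", function(object) {
  msg <- character()
  if (ncol(object@samples) != length(object@channelNames))
    msg <- c(msg, "number of channel names must equal number of columns")
  if (length(object@validMask) != nrow(object@samples))
    msg <- c(msg, "validMask length must equal the time axis")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!object@referenced && !is.na(object@centralChannel) &&
      !(object@centralChannel %in% object@channelNames))
    msg <- c(msg, "centralChannel must be one of the channel labels")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EegRecording
#'
#' @param samples numeric matrix (time x electrodes), in uV.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames electrode labels; defaults to `E1..En` with the middle
#'   electrode designated central.
#' @param centralChannel label of the central electrode.
#' @param validMask logical per-sample validity; defaults to all valid.
#' @param referenced whether the matrix already holds re-referenced channels.
#' @return An [EegRecording-class] object.
#' @examples
#' rec <- eegRecording(matrix(rnorm(512 * 5), ncol = 5), 256)
#' nChannels(rec)
#' @export
eegRecording <- function(samples, samplingRate,
                         channelNames = NULL,
                         centralChannel = NULL,
                         validMask = NULL,
                         referenced = FALSE) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelNames)) {
    channelNames <- if (!is.null(colnames(samples))) colnames(samples)
                    else paste0("E", seq_len(ncol(samples)))
  }
  if (is.null(centralChannel)) {
    centralChannel <- if (referenced) NA_character_
                      else channelNames[ceiling(length(channelNames) / 2)]
  }
  if (is.null(validMask)) validMask <- rep(TRUE, nrow(samples))
  colnames(samples) <- channelNames
  new("EegRecording",
    samples = samples, samplingRate = as.numeric(samplingRate),
    channelNames = channelNames, centralChannel = centralChannel,
    validMask = validMask, referenced = referenced)
}

#' @describeIn EegRecording-class sample matrix (time x channels, uV)
#' @param object,x an `EegRecording`
#' @export
setGeneric("eegSamples", function(object) standardGeneric("eegSamples"))
#' @rdname EegRecording-class
#' @export
setMethod("eegSamples", "EegRecording", function(object) object@samples)

#' @describeIn EegRecording-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EegRecording-class
#' @export
setMethod("samplingRate", "EegRecording", function(object) object@samplingRate)

#' @describeIn EegRecording-class electrode labels
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname EegRecording-class
#' @export
setMethod("channelNames", "EegRecording", function(object) object@channelNames)

#' @describeIn EegRecording-class per-sample validity mask
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname EegRecording-class
#' @export
setMethod("validMask", "EegRecording", function(object) object@validMask)

#' @describeIn EegRecording-class number of channels
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname EegRecording-class
#' @export
setMethod("nChannels", "EegRecording", function(object) ncol(object@samples))

#' @describeIn EegRecording-class duration in seconds
#' @export
setGeneric("recordDuration", function(object) standardGeneric("recordDuration"))
#' @rdname EegRecording-class
#' @export
setMethod("recordDuration", "EegRecording",
          function(object) nrow(object@samples) / object@samplingRate)

setMethod("show", "EegRecording", function(object) {
  cat(sprintf("EegRecording: %d channels x %.1f s @ %g Hz%s\n",
      ncol(object@samples), recordDuration(object), object@samplingRate,
      if (object@referenced) " (re-referenced)" else ""))
  cat(sprintf("  channels: %s%s\n", paste(object@channelNames, collapse = ", "),
      if (!object@referenced && !is.na(object@centralChannel))
        sprintf(" [central: %s]", object@centralChannel) else ""))
  cat(sprintf("  valid samples: %d / %d\n",
      sum(object@validMask), length(object@validMask)))
})

#' Seizure annotations
#'
#' Seizure onset/offset annotations are carried as a plain `data.frame` with
#' numeric columns `onset` and `offset` (seconds from record start). This
#' helper validates and normalizes such a table.
#'
#' @param onset numeric vector of onsets (s), or a two-column data.frame.
#' @param offset numeric vector of offsets (s).
#' @return data.frame with columns `onset`, `offset`, sorted by onset.
#' @examples
#' seizureAnnotations(c(10, 60), c(25, 80))
#' @export
seizureAnnotations <- function(onset, offset = NULL) {
  if (is.data.frame(onset)) {
    ann <- onset
    stopifnot(all(c("onset", "offset") %in% names(ann)))
  } else {
    ann <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset))
  }
  if (nrow(ann)) {
    if (any(ann$offset <= ann$onset))
      stop("each seizure offset must be greater than its onset")
    ann <- ann[order(ann$onset), , drop = FALSE]
    if (nrow(ann) > 1 && any(ann$onset[-1] < ann$offset[-nrow(ann)]))
      stop("seizure intervals must be non-overlapping")
  }
  rownames(ann) <- NULL
  ann[, c("onset", "offset")]
}

# ---- energy model containers ----

#' Operation ledger
#'
#' The unit of account of the energy model: counts of loads, stores and each
#' arithmetic-operation class incurred by one component (a feature, a network
#' layer, a classifier stage) during a single classification. Ledgers add
#' componentwise with `+`.
#'
#' @slot component component label.
#' @slot counts named numeric vector over the operation classes
#'   `load, store, mac, float_add, float_mult, float_div, int_add, int_mult,
#'   compare, onecycle`. A `mac` is a fused multiply-accumulate: it is counted
#'   as one arithmetic operation and costed as one float add plus one float
#'   multiply.
#' @seealso [opLedger()], [totalEnergy()], [operationCosts()]
#' @export
setClass("OpLedger",
  representation(component = "character", counts = "numeric"))

.opClasses <- c("load", "store", "mac", "float_add", "float_mult",
                "float_div", "int_add", "int_mult", "compare", "onecycle")

setValidity("OpLedger", function(object) {
  if (!identical(names(object@counts), .opClasses))
    return("counts must be named exactly by the operation classes")
  if (any(object@counts < 0)) return("all counts must be non-negative")
  TRUE
})

#' Construct an operation ledger
#'
#' @param component component label.
#' @param ... named counts among the operation classes (see [OpLedger-class]);
#'   omitted classes default to zero.
#' @return An [OpLedger-class].
#' @examples
#' opLedger("mean", load = 256, float_add = 255, float_mult = 1, store = 1)
#' @export
opLedger <- function(component = "total", ...) {
  counts <- stats::setNames(numeric(length(.opClasses)), .opClasses)
  add <- c(...)
  if (length(add)) {
    bad <- setdiff(names(add), .opClasses)
    if (length(bad)) stop("unknown operation class: ", paste(bad, collapse = ", "))
    counts[names(add)] <- counts[names(add)] + add
  }
  new("OpLedger", component = component, counts = counts)
}

#' @rdname OpLedger-class
#' @param e1,e2 ledgers to add
#' @export
setMethod("+", signature("OpLedger", "OpLedger"), function(e1, e2) {
  new("OpLedger", component = paste(e1@component, e2@component, sep = "+"),
      counts = e1@counts + e2@counts)
})

#' Scale a ledger by an integer multiplicity
#' @param ledger an [OpLedger-class]
#' @param n multiplicity (e.g. number of channels or time steps)
#' @return scaled ledger
#' @export
scaleLedger <- function(ledger, n) {
  new("OpLedger", component = ledger@component, counts = ledger@counts * n)
}

setMethod("show", "OpLedger", function(object) {
  cat(sprintf("OpLedger <%s>\n", object@component))
  nz <- object@counts[object@counts > 0]
  if (length(nz)) print(nz) else cat("  (empty)\n")
})

#' Per-operation energy costs
#'
#' Energy cost per memory access and per arithmetic-operation class in pJ,
#' as assumed for a 45 nm process. The defaults are the study's working
#' values: memory access 5 pJ, int32 add 0.1, int32 mult 3.1, float32 add 0.9,
#' float32 mult 3.7, compare 0.9, float32 divide 26.3 (square root is costed
#' the same, after the Cortex-M4F FPU cycle counts), and a generic one-cycle
#' float op 3.7.
#'
#' @param memory,int_add,int_mult,float_add,float_mult,compare,float_div,onecycle
#'   per-operation energies in pJ.
#' @return named numeric vector of costs (pJ).
#' @examples
#' operationCosts()
#' @export
operationCosts <- function(memory = 5, int_add = 0.1, int_mult = 3.1,
                           float_add = 0.9, float_mult = 3.7,
                           compare = 0.9, float_div = 26.3, onecycle = 3.7) {
  c(memory = memory, int_add = int_add, int_mult = int_mult,
    float_add = float_add, float_mult = float_mult, compare = compare,
    float_div = float_div, onecycle = onecycle)
}

#' Energy report
#'
#' Per-component operation ledgers for one classification of one detector,
#' with the energy cost table used to convert counts to energy.
#'
#' @slot detector detector label ("rf", "cnn" or "rnn").
#' @slot ledgers list of [OpLedger-class] objects, one per component.
#' @slot costs named cost vector from [operationCosts()].
#' @seealso [rfOpCounts()], [cnnOpCounts()], [rnnOpCounts()]
#' @export
setClass("EnergyReport",
  representation(detector = "character", ledgers = "list", costs = "numeric"))

setValidity("EnergyReport", function(object) {
  if (!all(vapply(object@ledgers, is, logical(1), "OpLedger")))
    return("ledgers must all be OpLedger objects")
  TRUE
})

setMethod("show", "EnergyReport", function(object) {
  cat(sprintf("EnergyReport <%s>: %d components\n",
              object@detector, length(object@ledgers)))
  df <- as.data.frame(object)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("  total: %.4g uJ | %.4g k AOs | %.4g k MAs\n",
      totalEnergy(object) / 1e6, aoCount(object) / 1e3, maCount(object) / 1e3))
})

#' Tabulate an energy report
#'
#' @param x an [EnergyReport-class]
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return data.frame with one row per component: arithmetic operations,
#'   memory accesses and energy (pJ).
#' @export
as.data.frame.EnergyReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    component = vapply(x@ledgers, function(l) l@component, character(1)),
    arithmetic_ops = vapply(x@ledgers, aoCount, numeric(1)),
    memory_accesses = vapply(x@ledgers, maCount, numeric(1)),
    energy_pJ = vapply(x@ledgers, totalEnergy, numeric(1), costs = x@costs),
    stringsAsFactors = FALSE
  )
}

#' Hardware calibration fit
#'
#' Result of regressing measured per-classification energies on model
#' estimates: `measured = offset + slope * estimated`.
#'
#' @slot slope unitless hardware scaling factor (b1).
#' @slot offset static offset in the measurement units (b0).
#' @slot adjR2 adjusted coefficient of determination.
#' @slot pearsonR Pearson correlation between estimates and measurements.
#' @slot fit the underlying `lm` fit.
#' @seealso [calibrateHardware()]
#' @export
setClass("CalibrationFit",
  representation(slope = "numeric", offset = "numeric", adjR2 = "numeric",
                 pearsonR = "numeric", fit = "ANY"))

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit: measured = %.4g + %.4g * estimated\n",
              object@offset, object@slope))
  cat(sprintf("  adjusted R^2 = %.4f, Pearson r = %.4f\n",
              object@adjR2, object@pearsonR))
})
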