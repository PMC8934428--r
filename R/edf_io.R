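# Minimal European Data Format (EDF) writer/reader for multichannel EEG:
# 16-bit samples, physical dimension uV, one data record per second. Covers
# the subset of the format this package produces and consumes.

#' Write a recording to an EDF file
#'
#' Serializes the sample matrix as standard 16-bit EDF with physical
#' dimension uV and 1 s data records. The physical range is taken from the
#' data (symmetric), the digital range is -32768..32767. A trailing partial
#' second is dropped, as EDF stores whole data records.
#'
#' @param recording an [EegRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEdf()]
#' @export
writeEdf <- function(recording, path) {
  stopifnot(is(recording, "EegRecording"))
  fs <- round(recording@samplingRate)
  ns <- ncol(recording@samples)
  nRec <- nrow(recording@samples) %/% fs
  x <- recording@samples[seq_len(nRec * fs), , drop = FALSE]
  physMax <- max(1, ceiling(max(abs(x))))
  pad <- function(s, w) formatC(substr(s, 1, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256 + 256 * ns), 8), pad("", 44),
    pad(as.character(nRec), 8), pad("1", 8), pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", w),
                                            collapse = ""), con, eos = NULL)
  fld(recording@channelNames, 16)
  fld(rep("synthetic EEG", ns), 80)
  fld(rep("uV", ns), 8)
  fld(rep(as.character(-physMax), ns), 8)
  fld(rep(as.character(physMax), ns), 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)
  fld(rep(as.character(fs), ns), 8)
  fld(rep("", ns), 32)
  # the standard affine map between physical and digital ranges
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round((x[idx, , drop = FALSE] + physMax) / (2 * physMax) * 65535 -
                   32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [writeEdf()]
#'
#' @param path EDF file path.
#' @return an [EegRecording-class] (validity mask all TRUE).
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  rd(8)
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  fs <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  stopifnot(length(unique(fs)) == 1)
  out <- matrix(0, nRec * fs[1], ns)
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = fs[s], size = 2, endian = "little")
      phys <- physMin[s] + (dig - digMin[s]) *
        (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
      out[((r - 1) * fs[1] + 1):(r * fs[1]), s] <- phys
    }
  }
  eegRecording(out, fs[1], channelNames = labels)
}

#' Write seizure annotations to CSV
#'
#' Two columns, `onset_s` and `offset_s`.
#' @param annotations annotation data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.csv(data.frame(onset_s = annotations$onset,
                              offset_s = annotations$offset),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read seizure annotations from CSV
#' @param path CSV with columns `onset_s`, `offset_s`.
#' @return annotation data.frame (onset/offset).
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path)
  seizureAnnotations(df$onset_s, df$offset_s)
}

#' Serialize the validity mask as an interval table
#'
#' Writes the invalid stretches of a recording as a BED-like CSV
#' (`start_s`, `end_s`, `reason`).
#'
#' @param recording an [EegRecording-class].
#' @param path output CSV path.
#' @param reason label recorded for each interval.
#' @return `path`, invisibly.
#' @export
writeMaskIntervals <- function(recording, path, reason = "invalid") {
  fs <- recording@samplingRate
  bad <- !recording@validMask
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  df <- data.frame(start_s = (starts[keep] - 1) / fs,
                   end_s = ends[keep] / fs,
                   reason = if (any(keep)) reason else character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
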