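# Minimal EDF (European Data Format) reader/writer for continuous
# equal-rate multichannel records: ASCII header (256 bytes + 256 per
# signal), 16-bit little-endian samples in fixed-duration data records.
# Covers plain EDF only (no EDF+ annotations, no per-signal rates).

.edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a multichannel record as EDF
#'
#' Stores the record as plain EDF with 1-s data records and per-channel
#' linear scaling to the full 16-bit digital range (quantization error is
#' about 3e-5 of the channel's amplitude range).
#'
#' @param record Numeric channels x samples matrix with channel names as row
#'   names; the sample count must be a multiple of `fs`.
#' @param fs Sampling rate in Hz (integer).
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_edf <- function(record, fs, path) {
  if (!is.matrix(record) || is.null(rownames(record))) {
    stop("record must be a matrix with channel names as row names")
  }
  fs <- as.integer(fs)
  ns <- nrow(record)
  if (ncol(record) %% fs != 0) stop("sample count must be a multiple of fs")
  n_rec <- ncol(record) %/% fs
  pmin_ <- apply(record, 1, min)
  pmax_ <- apply(record, 1, max)
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("synthetic", 80), .edf_pad("synthetic", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4)
  )
  sig_hdr <- paste0(
    paste(.edf_pad(rownames(record), 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(.edf_pad(sprintf("%.6g", pmin_), 8), collapse = ""),
    paste(.edf_pad(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "") # reserved
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ci in seq_len(ns)) {
      dig <- as.integer(round((record[ci, cols] - pmin_[ci]) * scale[ci]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF record
#'
#' @param path EDF file path.
#' @return List with `record` (channels x samples matrix, channel names as
#'   row names) and `fs` (sampling rate in Hz).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  rd(80 * ns)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  rd(32 * ns) # reserved
  if (length(unique(spr)) != 1) stop("per-signal sampling rates not supported")
  fs <- spr[1] / dur
  record <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ci in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      record[ci, cols] <- pmin_[ci] +
        (dig - dmin[ci]) * (pmax_[ci] - pmin_[ci]) / (dmax[ci] - dmin[ci])
    }
  }
  list(record = record, fs = fs)
}
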