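#' @name edf_io
#' @title Minimal EDF (European Data Format) reader and writer
#'
#' @description
#' Continuous 16-bit EDF with one-second data records, sufficient for the
#' TUH-style recordings this package emulates (integer sampling rates, one
#' common rate across channels). Physical values are stored in microvolts;
#' round-tripping is exact up to the 16-bit quantization step.
NULL

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

num_ascii8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 0)
    if (nchar(s) <= 8) return(pad_ascii(s, 8))
  }
  pad_ascii(formatC(x, digits = 1, format = "g"), 8)
}

#' Write an EDF file
#'
#' @param rec An [eeg_recording()]; `rec$fs` must be a whole number of Hz.
#'   The signal is truncated to a whole number of one-second records.
#' @param path Output file path.
#' @param patient,recording_info Free-text header fields (80 bytes each).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X X X X",
                      recording_info = "Startdate 01-JAN-2000") {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmax_abs <- max(abs(data), 1e-6)
  phys_min <- -pmax_abs; phys_max <- pmax_abs
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii(patient, 80), pad_ascii(recording_info, 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(hdr_bytes, 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii("1", 8), pad_ascii(ns, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste0(pad_ascii(rec$channels, 16), collapse = ""),
    paste0(rep(pad_ascii("", 80), ns), collapse = ""),
    paste0(rep(pad_ascii("uV", 8), ns), collapse = ""),
    paste0(rep(num_ascii8(phys_min), ns), collapse = ""),
    paste0(rep(num_ascii8(phys_max), ns), collapse = ""),
    paste0(rep(pad_ascii(dig_min, 8), ns), collapse = ""),
    paste0(rep(pad_ascii(dig_max, 8), ns), collapse = ""),
    paste0(rep(pad_ascii("", 80), ns), collapse = ""),
    paste0(rep(pad_ascii(fs, 8), ns), collapse = ""),
    paste0(rep(pad_ascii("", 32), ns), collapse = "")
  ), con, eos = NULL)

  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t(data[, cols, drop = FALSE])     # samples x channels
    dig <- round((block - phys_min) * gain) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  if (length(unique(spr)) != 1)
    stop("read_edf: channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t((block - rep(dig_min, each = spr[1])) *
                        rep(gain, each = spr[1]) +
                        rep(phys_min, each = spr[1]))
  }
  eeg_recording(data, labels, fs, id = basename(path))
}
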