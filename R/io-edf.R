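#' Write a recording to a 16-bit EDF file
#'
#' European Data Format: 256-byte fixed header, 256 bytes per signal,
#' then 1-s data records of 16-bit little-endian integers. Samples are
#' scaled to a symmetric physical range (uV) chosen from the data, so
#' the round-trip quantization error is at most half of
#' `(physical range) / 2^16`. Recordings whose length is not a whole
#' number of records are zero-padded on disk; the true sample count is
#' stored in the reserved header field and honoured by [read_edf()].
#'
#' @param recording An [eeg_recording()]. `fs` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("format error: EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  data <- recording$data
  ns <- nrow(data)
  if (ns == 0L) stop("format error: empty channel list")
  n <- ncol(data)
  n_rec <- as.integer(ceiling(n / fs))

  pm <- signif(max(abs(data), 1e-6) * 1.001, 4)
  dig_max <- 32767L
  scaled <- round(data / pm * dig_max)
  scaled[scaled > dig_max] <- dig_max
  scaled[scaled < -dig_max] <- -dig_max

  pad <- function(x, width) {
    x <- strtrim(as.character(x), width)
    formatC(x, width = width, flag = "-")
  }
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(recording$subject_id, 80)
  wr("preshot synthetic recording", 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(header_bytes, 8)
  wr(sprintf("NSAMP=%d", n), 44)  # reserved: true per-signal sample count
  wr(n_rec, 8)
  wr(1, 8)
  wr(ns, 4)
  wr_all <- function(vals, width) for (v in vals) wr(v, width)
  wr_all(recording$channel_labels, 16)
  wr_all(rep("", ns), 80)
  wr_all(rep("uV", ns), 8)
  wr_all(rep(format(-pm), ns), 8)
  wr_all(rep(format(pm), ns), 8)
  wr_all(rep(-dig_max, ns), 8)
  wr_all(rep(dig_max, ns), 8)
  wr_all(rep("BP:0.0-inf", ns), 80)
  wr_all(rep(fs, ns), 8)
  wr_all(rep("", ns), 32)

  total <- n_rec * fs
  if (total > n) {
    scaled <- cbind(scaled, matrix(0L, nrow = ns, ncol = total - n))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(scaled[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_header_field <- function(con, width, what, offset, numeric = FALSE) {
  raw <- readChar(con, width, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < width)
    stop("format error: truncated EDF header while reading ", what,
         " at byte offset ", offset)
  val <- trimws(raw)
  if (numeric) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop("format error: non-numeric ", what, " ('", val,
           "') at byte offset ", offset)
    return(num)
  }
  val
}

#' Read a 16-bit EDF file
#'
#' Rejects malformed headers (with the byte offset of the offending
#' field) and silently truncated files rather than returning partial
#' data. Requires all signals to share one sampling rate, which is the
#' layout [write_edf()] produces.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_header_field(con, 8, "version", 0)
  if (version != "0")
    stop("format error: unsupported EDF version '", version,
         "' at byte offset 0")
  patient <- read_header_field(con, 80, "patient id", 8)
  read_header_field(con, 80, "recording id", 88)
  read_header_field(con, 8, "start date", 168)
  read_header_field(con, 8, "start time", 176)
  header_bytes <- read_header_field(con, 8, "header size", 184,
                                    numeric = TRUE)
  reserved <- read_header_field(con, 44, "reserved", 192)
  n_rec <- read_header_field(con, 8, "record count", 236, numeric = TRUE)
  rec_dur <- read_header_field(con, 8, "record duration", 244,
                               numeric = TRUE)
  ns <- read_header_field(con, 4, "signal count", 252, numeric = TRUE)
  if (ns < 1) stop("format error: signal count < 1 at byte offset 252")
  ns <- as.integer(ns)

  rd_all <- function(width, what, base, numeric = FALSE) {
    vapply(seq_len(ns), function(i) {
      read_header_field(con, width, what, base + (i - 1L) * width,
                        numeric = FALSE)
    }, character(1))
  }
  base <- 256L
  labels <- rd_all(16, "label", base); base <- base + 16L * ns
  rd_all(80, "transducer", base); base <- base + 80L * ns
  rd_all(8, "dimension", base); base <- base + 8L * ns
  pmin_ <- as.numeric(rd_all(8, "physical min", base)); base <- base + 8L * ns
  pmax_ <- as.numeric(rd_all(8, "physical max", base)); base <- base + 8L * ns
  dmin_ <- as.numeric(rd_all(8, "digital min", base)); base <- base + 8L * ns
  dmax_ <- as.numeric(rd_all(8, "digital max", base)); base <- base + 8L * ns
  rd_all(80, "prefiltering", base); base <- base + 80L * ns
  spr <- as.numeric(rd_all(8, "samples per record", base))
  base <- base + 8L * ns
  rd_all(32, "signal reserved", base)
  if (anyNA(pmin_) || anyNA(pmax_) || anyNA(dmin_) || anyNA(dmax_) ||
      anyNA(spr))
    stop("format error: non-numeric signal scaling fields in EDF header")
  if (length(unique(spr)) != 1L)
    stop("format error: mixed per-signal sampling rates are not supported")
  spr <- as.integer(spr[1])
  if (header_bytes != 256L + 256L * ns)
    stop("format error: header size field inconsistent with signal count")

  n_rec <- as.integer(n_rec)
  expected <- as.double(n_rec) * ns * spr * 2
  payload <- file.size(path) - header_bytes
  if (payload < expected)
    stop("format error: truncated EDF file (", payload,
         " payload bytes, expected ", expected, ")")

  raw_vals <- readBin(con, integer(), n = n_rec * ns * spr, size = 2L,
                      signed = TRUE, endian = "little")
  if (length(raw_vals) < n_rec * ns * spr)
    stop("format error: truncated EDF record payload")
  data <- matrix(0, nrow = ns, ncol = n_rec * spr)
  for (r in seq_len(n_rec)) {
    block <- raw_vals[((r - 1L) * ns * spr + 1L):(r * ns * spr)]
    data[, ((r - 1L) * spr + 1L):(r * spr)] <-
      t(matrix(block, nrow = spr, ncol = ns))
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- data * gain + (pmin_ - dmin_ * gain)

  nsamp <- sub("^NSAMP=", "", reserved)
  if (grepl("^NSAMP=", reserved) && !is.na(suppressWarnings(as.integer(nsamp)))) {
    n_true <- as.integer(nsamp)
    if (n_true <= ncol(data)) data <- data[, seq_len(n_true), drop = FALSE]
  }
  fs <- spr / rec_dur
  eeg_recording(data, fs, labels, subject_id = patient)
}
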