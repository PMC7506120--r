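# European Data Format (EDF): 256-byte fixed header, 256 bytes of signal
# headers per channel (field-major layout), then data records of 16-bit
# little-endian integers mapped linearly between the digital and physical
# ranges. Plain EDF is written; EDF+ files are readable (annotation channels
# are skipped).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a multi-channel EEG signal to an EDF file
#'
#' Writes plain 16-bit EDF. Samples are quantized onto the digital range
#' -32768..32767 spanning `phys_range`, so the round-trip error is at most
#' one quantization step of `diff(phys_range)/65535`.
#'
#' @param data Channels x samples numeric matrix (microvolts), or an
#'   [eeg_epoch].
#' @param path Output file path.
#' @param fs Sampling rate in Hz (ignored when `data` is an epoch).
#' @param channel_names Channel labels (ignored when `data` is an epoch).
#' @param phys_range Physical range in microvolts mapped onto the full
#'   digital range; the default +/-1000 uV covers 100-200 uV discharges with
#'   headroom.
#' @param record_seconds Duration of one EDF data record; the total duration
#'   must be an integer number of records.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, path, fs = NULL, channel_names = NULL,
                      phys_range = c(-1000, 1000), record_seconds = 1) {
  if (inherits(data, "eeg_epoch")) {
    fs <- data$fs
    channel_names <- data$channel_names
    data <- data$data
  }
  data <- as.matrix(data)
  if (is.null(fs)) stop("'fs' is required")
  if (is.null(channel_names)) channel_names <- rownames(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  ns <- nrow(data)
  spr <- fs * record_seconds              # samples per record per signal
  if (abs(spr - round(spr)) > 1e-9) stop("fs * record_seconds must be integer")
  spr <- as.integer(round(spr))
  if (ncol(data) %% spr != 0L)
    stop("total samples must be a whole number of EDF records")
  n_rec <- ncol(data) %/% spr
  if (any(data < phys_range[1] | data > phys_range[2]))
    stop("signal exceeds the EDF physical range; widen 'phys_range'")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                              # version
  wr("synthetic EEG", 80)                 # patient id
  wr("sdleeg", 80)                        # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)    # start date / time
  wr(256 * (ns + 1), 8)                   # header bytes
  wr("", 44)                              # reserved
  wr(n_rec, 8)
  wr(format(record_seconds), 8)
  wr(ns, 4)
  for (nm in channel_names) wr(nm, 16)
  for (k in seq_len(ns)) wr("", 80)       # transducer
  for (k in seq_len(ns)) wr("uV", 8)
  for (k in seq_len(ns)) wr(format(phys_range[1]), 8)
  for (k in seq_len(ns)) wr(format(phys_range[2]), 8)
  for (k in seq_len(ns)) wr(-32768, 8)
  for (k in seq_len(ns)) wr(32767, 8)
  for (k in seq_len(ns)) wr("", 80)       # prefiltering
  for (k in seq_len(ns)) wr(spr, 8)
  for (k in seq_len(ns)) wr("", 32)       # reserved

  scale <- 65535 / diff(phys_range)
  dig <- round((data - phys_range[1]) * scale) - 32768
  dig[] <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns))
      writeBin(as.integer(dig[s, idx]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n)
  if (length(raw) < n) stop("EDF format error: truncated header")
  trimws(rawToChar(raw))
}

read_num <- function(con, n) {
  v <- suppressWarnings(as.numeric(read_ascii(con, n)))
  if (is.na(v)) stop("EDF format error: non-numeric header field")
  v
}

#' Read an EDF file
#'
#' Parses the header, honours the per-channel physical/digital scaling, and
#' returns the signals in physical units (microvolts) with channel order
#' preserved. EDF+ annotation channels are skipped. All retained channels
#' must share one sampling rate.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return A list of class `eeg_recording` with elements `signals` (channels
#'   x samples matrix, uV), `fs` (Hz), and `channel_names`.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("EDF format error: file too short for header")
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (version != "0") stop("EDF format error: bad version field")
  read_ascii(con, 80); read_ascii(con, 80)   # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)     # date / time
  header_bytes <- read_num(con, 8)
  read_ascii(con, 44)
  n_rec <- read_num(con, 8)
  rec_dur <- read_num(con, 8)
  ns <- as.integer(read_num(con, 4))
  if (ns < 1) stop("EDF format error: no signals")
  if (header_bytes != 256 * (ns + 1))
    stop("EDF format error: inconsistent header size")

  labels <- vapply(seq_len(ns), function(k) read_ascii(con, 16), "")
  for (k in seq_len(ns)) read_ascii(con, 80)
  units <- vapply(seq_len(ns), function(k) read_ascii(con, 8), "")
  phys_min <- vapply(seq_len(ns), function(k) read_num(con, 8), 0)
  phys_max <- vapply(seq_len(ns), function(k) read_num(con, 8), 0)
  dig_min <- vapply(seq_len(ns), function(k) read_num(con, 8), 0)
  dig_max <- vapply(seq_len(ns), function(k) read_num(con, 8), 0)
  for (k in seq_len(ns)) read_ascii(con, 80)
  spr <- vapply(seq_len(ns), function(k) as.integer(read_num(con, 8)), 0L)
  for (k in seq_len(ns)) read_ascii(con, 32)

  expected <- header_bytes + n_rec * sum(spr) * 2
  if (sz < expected)
    stop("EDF format error: file truncated (expected ", expected,
         " bytes, found ", sz, ")")

  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (!any(keep)) stop("EDF format error: no signal channels")
  fs_all <- spr[keep] / rec_dur
  if (length(unique(fs_all)) > 1L)
    stop("unsupported input: mixed sampling rates across EEG channels")
  fs <- fs_all[1]

  n_rec <- as.integer(n_rec)
  out <- matrix(0, nrow = sum(keep), ncol = n_rec * spr[keep][1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[s]) stop("EDF format error: truncated record")
      if (keep[s]) {
        row <- sum(keep[seq_len(s)])
        idx <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
        out[row, idx] <- phys_min[s] + (raw - dig_min[s]) * gain[s]
      }
    }
  }
  rownames(out) <- labels[keep]
  structure(list(signals = out, fs = fs, channel_names = labels[keep],
                 units = units[keep]),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$signals), ncol(x$signals), x$fs))
  invisible(x)
}
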