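# Minimal EDF (European Data Format) reader/writer for two-channel
# polysomnography. Standard 16-bit EDF: 256-byte fixed header, 256 bytes per
# signal, then data records of little-endian int16 samples. One data record
# per second; fs must therefore be an integer and the recording an integer
# number of seconds.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

#' Write a two-channel recording as EDF
#'
#' Signals are quantized to 16 bits over a symmetric physical range covering
#' the data (physical unit microvolts). The EDF start time is taken from the
#' recording's start clock; the date is a placeholder since synthetic
#' recordings carry no calendar date.
#'
#' @param rec a [recording()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "sleep_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n <- length(rec$eeg)
  n_rec <- n %/% fs
  if (n_rec * fs != n) stop("EDF writer requires an integer number of seconds")
  sig <- list(EEG = rec$eeg, EMG = rec$emg)

  pmax <- vapply(sig, function(x) max(ceiling(max(abs(x)) + 1e-9), 1), 0)
  dig_min <- -32768; dig_max <- 32767
  gain <- (2 * pmax) / (dig_max - dig_min)

  writer <- function(out) {
    con <- file(out, "wb")
    on.exit(close(con))
    hdr <- paste0(
      edf_pad("0", 8),
      edf_pad("X", 80),
      edf_pad("Startdate X X X X", 80),
      edf_pad("01.01.01", 8),
      edf_pad(gsub(":", ".", format_clock(rec$start_clock)), 8),
      edf_pad(256 * (1 + length(sig)), 8),
      edf_pad("", 44),
      edf_pad(n_rec, 8),
      edf_pad("1", 8),
      edf_pad(length(sig), 4)
    )
    field <- function(vals, width) paste0(vapply(vals, edf_pad, "", width = width), collapse = "")
    hdr <- paste0(
      hdr,
      field(names(sig), 16),
      field(rep("", 2), 80),
      field(rep("uV", 2), 8),
      field(-pmax, 8),
      field(pmax, 8),
      field(rep(dig_min, 2), 8),
      field(rep(dig_max, 2), 8),
      field(rep("", 2), 80),
      field(rep(fs, 2), 8),
      field(rep("", 2), 32)
    )
    writeChar(hdr, con, eos = NULL)
    dig <- mapply(function(x, p, g) {
      d <- round((x + p) / g) + dig_min
      pmin(pmax(d, dig_min), dig_max)
    }, sig, pmax, gain, SIMPLIFY = FALSE)
    # interleave per one-second record: EEG block then EMG block
    out_mat <- rbind(matrix(dig$EEG, nrow = fs), matrix(dig$EMG, nrow = fs))
    writeBin(as.integer(out_mat), con, size = 2, endian = "little")
  }
  write_atomic(writer, path)
}

#' Read an EDF file
#'
#' Returns the raw channels (physical units), per-channel labels and sampling
#' rates, and the header start time. Channel-to-role mapping is done by
#' [read_recording()].
#'
#' @param path EDF file
#' @return list with `signals` (named list of numeric vectors), `fs`
#'   (per-channel sampling rates), `start_clock` (seconds from midnight)
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8)
  start <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16)
  fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  total <- sum(spr) * n_rec
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little")
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  signals <- lapply(seq_len(ns), function(i) {
    idx <- as.vector(outer(seq_len(spr[i]) + offs[i], (seq_len(n_rec) - 1L) * per_rec, "+"))
    d <- raw[idx]
    (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
  })
  names(signals) <- labels
  start_sec <- parse_clock(gsub("\\.", ":", start))
  list(signals = signals, fs = spr / rec_dur, start_clock = start_sec,
       labels = labels)
}
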