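#' Construct a two-channel polysomnography recording
#'
#' @param eeg,emg numeric vectors of equal length, in microvolts
#' @param fs sampling rate in Hz
#' @param start_clock clock time of the first sample (see [parse_clock()])
#' @param lights_on,lights_off light-schedule clock times; the defaults are
#'   lights on 08:00, lights off 20:00
#' @return an object of class `sleep_recording`
#' @export
recording <- function(eeg, emg, fs, start_clock = "20:00:00",
                      lights_on = "08:00", lights_off = "20:00") {
  if (length(eeg) != length(emg)) stop("eeg and emg must have equal length")
  if (fs <= 0) stop("fs must be positive")
  on <- parse_clock(lights_on); off <- parse_clock(lights_off)
  if (on == off) stop("lights_on and lights_off must differ")
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg), fs = fs,
                 start_clock = parse_clock(start_clock),
                 lights_on = on, lights_off = off),
            class = "sleep_recording")
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording> %d samples @ %g Hz (%.1f min), start %s, lights %s-%s\n",
              length(x$eeg), x$fs, length(x$eeg) / x$fs / 60,
              format_clock(x$start_clock), format_clock(x$lights_on),
              format_clock(x$lights_off)))
  invisible(x)
}

#' Read a recording from EDF or the raw-binary fallback
#'
#' EEG/EMG channels are located by case-insensitive label match; when the file
#' uses other labels, supply `channel_map`. The raw-binary fallback is a
#' float64 little-endian file holding the EEG block followed by the EMG block,
#' with a JSON sidecar (`<path>.json`) giving `fs`, `n_samples`, `channels`,
#' `start_clock` and the light schedule (written by [write_recording()]).
#'
#' @param path input file
#' @param format `"edf"` or `"raw"`
#' @param channel_map optional named character vector, e.g.
#'   `c(eeg = "eeg1", emg = "muscle")`, mapping roles to file labels
#' @param lights_on,lights_off light schedule (EDF carries none)
#' @return a [recording()]
#' @export
read_recording <- function(path, format = c("edf", "raw"), channel_map = NULL,
                           lights_on = "08:00", lights_off = "20:00") {
  format <- match.arg(format)
  if (format == "raw") {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("raw format needs sidecar config: ", side)
    meta <- jsonlite::fromJSON(side)
    con <- file(path, "rb")
    on.exit(close(con))
    dat <- readBin(con, "double", n = 2 * meta$n_samples, size = 8,
                   endian = "little")
    return(recording(dat[seq_len(meta$n_samples)],
                     dat[meta$n_samples + seq_len(meta$n_samples)],
                     fs = meta$fs, start_clock = meta$start_clock,
                     lights_on = meta$lights_on, lights_off = meta$lights_off))
  }
  edf <- read_edf(path)
  lab <- toupper(edf$labels)
  pick <- function(role) {
    if (!is.null(channel_map) && !is.null(channel_map[[tolower(role)]])) {
      i <- match(toupper(channel_map[[tolower(role)]]), lab)
    } else {
      i <- match(role, lab)
    }
    if (is.na(i)) {
      stop("no ", role, " channel found; file has channels: ",
           paste(edf$labels, collapse = ", "),
           " (use channel_map to override)")
    }
    i
  }
  i_eeg <- pick("EEG"); i_emg <- pick("EMG")
  if (edf$fs[i_eeg] != edf$fs[i_emg]) {
    stop("EEG and EMG sampling rates differ (", edf$fs[i_eeg], " vs ",
         edf$fs[i_emg], " Hz)")
  }
  recording(edf$signals[[i_eeg]], edf$signals[[i_emg]], fs = edf$fs[i_eeg],
            start_clock = edf$start_clock,
            lights_on = lights_on, lights_off = lights_off)
}

#' Write a recording to EDF or the raw-binary fallback
#'
#' @inheritParams read_recording
#' @param rec a [recording()]
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, format = c("edf", "raw")) {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(rec, path))
  meta <- list(fs = rec$fs, n_samples = length(rec$eeg),
               channels = c("EEG", "EMG"), dtype = "float64",
               layout = "channel-blocks",
               start_clock = rec$start_clock,
               lights_on = rec$lights_on, lights_off = rec$lights_off)
  write_atomic(function(p) {
    con <- file(p, "wb")
    on.exit(close(con))
    writeBin(c(rec$eeg, rec$emg), con, size = 8, endian = "little")
  }, path)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' there is no group delay and epoch boundaries stay aligned between EEG and
#' EMG. When the requested upper edge reaches or exceeds Nyquist it is capped
#' at `0.98 * fs/2` (a 15-300 Hz analog EMG band becomes 15-62.7 Hz at
#' fs = 128); the effective band is attached as attribute `"effective_band"`.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param low,high band edges (Hz); `0 < low < high`, `low < fs/2`
#' @return filtered signal with attribute `effective_band`
#' @export
bandpass <- function(x, fs, low, high) {
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (low >= fs / 2) stop("low edge must be below Nyquist (", fs / 2, " Hz)")
  eff_high <- if (high >= fs / 2) 0.98 * fs / 2 else high
  bf <- signal::butter(4, c(low, eff_high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  attr(y, "effective_band") <- c(low = low, high = eff_high)
  y
}

#' Segment a recording into fixed-length epochs
#'
#' Epochs are contiguous, non-overlapping, anchored at sample 0 of the
#' recording: epoch `k` (0-based) covers samples `[k*L, (k+1)*L)` with
#' `L = epoch_len * fs`. A trailing remainder shorter than one epoch is
#' dropped (recorded in attribute `dropped_samples`).
#'
#' @param rec a [recording()]
#' @param epoch_len epoch length in seconds (default 4)
#' @return an `epoch_series`: list with `eeg`/`emg` sample matrices
#'   (`L x n_epochs`), `epoch_clock` (start clock of each epoch, seconds from
#'   midnight) and `phase` (`"light"`/`"dark"` by epoch start)
#' @export
epoch_segment <- function(rec, epoch_len = 4) {
  L <- epoch_len * rec$fs
  if (L != round(L)) stop("epoch_len * fs must be an integer")
  L <- as.integer(L)
  n <- length(rec$eeg) %/% L
  if (n < 1) stop("recording shorter than one epoch")
  dropped <- length(rec$eeg) - n * L
  keep <- seq_len(n * L)
  clock <- (rec$start_clock + (seq_len(n) - 1L) * epoch_len) %% 86400L
  phase <- ifelse(in_light_phase(clock, rec$lights_on, rec$lights_off),
                  "light", "dark")
  structure(list(
    eeg = matrix(rec$eeg[keep], nrow = L),
    emg = matrix(rec$emg[keep], nrow = L),
    fs = rec$fs, epoch_len = epoch_len,
    start_clock = rec$start_clock,
    lights_on = rec$lights_on, lights_off = rec$lights_off,
    epoch_clock = clock, phase = phase,
    dropped_samples = dropped
  ), class = "epoch_series")
}

#' Construct a hypnogram
#'
#' A per-epoch vector of vigilance-state labels with the metadata needed to
#' place epochs in clock time.
#'
#' @param labels character vector of states in
#'   `r paste(VIGILANCE_STATES, collapse = ", ")`
#' @param epoch_len epoch length (s)
#' @param start_clock clock time of epoch 0
#' @param lights_on,lights_off light schedule
#' @param provenance one of `"auto"`, `"truth"`, `"corrected"`
#' @param references the [scoring_references()] used, if auto-scored
#' @return character vector of class `hypnogram`
#' @export
hypnogram <- function(labels, epoch_len = 4, start_clock = "20:00",
                      lights_on = "08:00", lights_off = "20:00",
                      provenance = "auto", references = NULL) {
  bad <- !is.na(labels) & !labels %in% VIGILANCE_STATES
  if (any(bad)) {
    stop("unknown state token(s): ", paste(unique(labels[bad]), collapse = ", "))
  }
  structure(as.character(labels),
            epoch_len = epoch_len, start_clock = parse_clock(start_clock),
            lights_on = parse_clock(lights_on),
            lights_off = parse_clock(lights_off),
            provenance = provenance, references = references,
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs (%s), start %s\n", length(x),
              attr(x, "epoch_len"), attr(x, "provenance"),
              format_clock(attr(x, "start_clock"))))
  print(table(factor(unclass(x), levels = VIGILANCE_STATES)))
  invisible(x)
}

hyp_epoch_clock <- function(hyp) {
  (attr(hyp, "start_clock") +
     (seq_along(hyp) - 1L) * attr(hyp, "epoch_len")) %% 86400L
}

#' Write / read a hypnogram as TSV
#'
#' Three tab-separated columns: `epoch_index` (0-based), `clock_time`
#' (HH:MM:SS of the epoch start) and `state`. Round-trips losslessly.
#'
#' @param hyp a [hypnogram()]
#' @param path TSV file
#' @return `path` invisibly (write); a [hypnogram()] (read)
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp) - 1L,
                   clock_time = format_clock(hyp_epoch_clock(hyp)),
                   state = unclass(hyp))
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_hypnogram
#' @param epoch_len,lights_on,lights_off metadata not stored in the TSV
#' @export
read_hypnogram <- function(path, epoch_len = 4, lights_on = "08:00",
                           lights_off = "20:00") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "character"))
  if (nrow(df) == 0) {
    return(hypnogram(character(0), epoch_len = epoch_len,
                     start_clock = 0, lights_on = lights_on,
                     lights_off = lights_off, provenance = "auto"))
  }
  bad <- which(!df$state %in% VIGILANCE_STATES)
  if (length(bad)) {
    stop("unknown state token '", df$state[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path)
  }
  if (!identical(df$epoch_index, seq_len(nrow(df)) - 1L)) {
    stop("non-contiguous epoch indices in ", path)
  }
  hypnogram(df$state, epoch_len = epoch_len,
            start_clock = df$clock_time[1],
            lights_on = lights_on, lights_off = lights_off,
            provenance = "auto")
}
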