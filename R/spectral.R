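#' Default EEG band edges (Hz)
#'
#' Half-open integer-bin bands: delta `[1,6)`, theta `[6,11)`, alpha `[11,16)`,
#' beta `[16,31)`. Delta and theta follow the 1-Hz-resolution convention for
#' rodent sleep scoring (delta bins 1-5 Hz, theta bins 6-10 Hz); alpha and
#' beta are the conventional rodent continuation. All edges are overridable.
#'
#' @return named list of `c(low, high)` pairs
#' @export
default_band_edges <- function() {
  list(delta = c(1, 6), theta = c(6, 11), alpha = c(11, 16), beta = c(16, 31))
}

# Periodogram of Hann-windowed epochs, native resolution fs/N Hz.
# Columns of `m` are epochs. Normalised so that the sum of one-sided bins
# equals the mean square of the windowed signal (Parseval).
psd_native <- function(m, fs) {
  N <- nrow(m)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1L) / N)
  X <- stats::mvfft(m * w)
  half <- N %/% 2
  P <- Mod(X[seq_len(half + 1L), , drop = FALSE])^2 / N^2
  P[2:half, ] <- 2 * P[2:half, , drop = FALSE]
  rownames(P) <- NULL
  attr(P, "freq") <- (0:half) * fs / N
  P
}

# Aggregate native bins into 1-Hz bins centered on integers:
# bin f sums native bins with frequency in [f - 0.5, f + 0.5).
aggregate_1hz <- function(P, f_max = 31) {
  freq <- attr(P, "freq")
  centers <- 0:min(f_max, floor(max(freq)))
  out <- vapply(centers, function(f) {
    sel <- freq >= f - 0.5 & freq < f + 0.5
    colSums(P[sel, , drop = FALSE])
  }, numeric(ncol(P)))
  out <- t(matrix(out, ncol = length(centers)))
  rownames(out) <- centers
  out
}

#' Per-epoch power spectral density in 1-Hz bins
#'
#' FFT periodogram of the Hann-windowed 4-s epoch. Native 0.25-Hz bins (at
#' fs = 128 and 4-s epochs) are summed into 1-Hz bins centered on integer
#' frequencies; total power over the aggregated range is conserved exactly.
#'
#' @param eeg_epoch one epoch of EEG samples
#' @param fs sampling rate (Hz)
#' @param f_max highest 1-Hz bin to return (default 31, covering the beta
#'   band)
#' @return named numeric vector, 1-Hz bins `0 ... f_max` (microvolts squared);
#'   attribute `"native"` holds the unaggregated periodogram with its
#'   `"freq"` attribute
#' @export
epoch_psd <- function(eeg_epoch, fs, f_max = 31) {
  if (any(!is.finite(eeg_epoch))) stop("epoch contains non-finite samples")
  P <- psd_native(matrix(eeg_epoch, ncol = 1), fs)
  out <- aggregate_1hz(P, f_max)[, 1]
  native <- P[, 1]
  attr(native, "freq") <- attr(P, "freq")
  attr(out, "native") <- native
  out
}

#' Band powers, band fractions and the theta fraction
#'
#' Band power is the sum of the member 1-Hz bins (half-open `[low, high)` on
#' bin centers); band fractions are each band's share of the four-band total;
#' `theta_fraction` is theta power over total 1-30 Hz power (the denominator
#' used by the REM/cataplexy "over 50 percent theta" rule; configurable by
#' overriding `total_range`).
#'
#' @param psd_1hz vector (or matrix, bins x epochs) of 1-Hz bin powers with
#'   bin-center names as produced by [epoch_psd()]
#' @param band_edges see [default_band_edges()]
#' @param total_range range (Hz) of the theta-fraction denominator
#' @return data.frame with one row per epoch: band powers, `frac_*`,
#'   `theta_fraction`. All-zero spectra yield `NA` fractions (flagged
#'   missing, not zero).
#' @export
band_powers <- function(psd_1hz, band_edges = default_band_edges(),
                        total_range = c(1, 31)) {
  if (is.null(dim(psd_1hz))) psd_1hz <- matrix(psd_1hz, ncol = 1,
                                               dimnames = list(names(psd_1hz)))
  centers <- as.numeric(rownames(psd_1hz))
  if (max(centers) + 1 < max(vapply(band_edges, max, 0))) {
    stop("PSD does not cover the requested bands")
  }
  bp <- vapply(band_edges, function(e) {
    colSums(psd_1hz[centers >= e[1] & centers < e[2], , drop = FALSE])
  }, numeric(ncol(psd_1hz)))
  bp <- matrix(bp, ncol = length(band_edges),
               dimnames = list(NULL, names(band_edges)))
  four <- rowSums(bp)
  frac <- bp / ifelse(four > 0, four, NA_real_)
  colnames(frac) <- paste0("frac_", names(band_edges))
  tot <- colSums(psd_1hz[centers >= total_range[1] & centers < total_range[2],
                         , drop = FALSE])
  theta_fraction <- ifelse(tot > 0, bp[, "theta"] / tot, NA_real_)
  cbind(as.data.frame(bp), as.data.frame(frac),
        data.frame(theta_fraction = theta_fraction))
}

#' EMG integral of one epoch
#'
#' Mean rectified EMG amplitude times epoch length: the muscle-tone proxy.
#'
#' @param emg_epoch one epoch of EMG samples
#' @param fs sampling rate (Hz)
#' @return microvolt-seconds
#' @export
emg_integral <- function(emg_epoch, fs) {
  if (any(!is.finite(emg_epoch))) stop("epoch contains non-finite samples")
  mean(abs(emg_epoch)) * length(emg_epoch) / fs
}

#' Per-epoch feature table
#'
#' Computes the 1-Hz PSD, band powers/fractions, theta fraction and EMG
#' integral for every epoch of an [epoch_segment()] result. The PSD matrix is
#' attached as attribute `"psd_1hz"` (and `"psd_native"` when
#' `keep_native = TRUE`) for state-spectrum summaries.
#'
#' @param es an `epoch_series`
#' @param band_edges see [default_band_edges()]
#' @param total_range theta-fraction denominator range (Hz)
#' @param keep_native also keep the native 0.25-Hz periodogram
#' @return data.frame, one row per epoch: `epoch_index` (0-based), `clock`,
#'   `phase`, band powers, fractions, `theta_fraction`, `emg_integral`
#' @export
epoch_features <- function(es, band_edges = default_band_edges(),
                           total_range = c(1, 31), keep_native = FALSE) {
  P <- psd_native(es$eeg, es$fs)
  psd1 <- aggregate_1hz(P, 31)
  out <- cbind(
    data.frame(epoch_index = seq_len(ncol(es$eeg)) - 1L,
               clock = es$epoch_clock, phase = es$phase),
    band_powers(psd1, band_edges, total_range),
    data.frame(emg_integral = colMeans(abs(es$emg)) * es$epoch_len)
  )
  attr(out, "psd_1hz") <- psd1
  if (keep_native) attr(out, "psd_native") <- P
  attr(out, "band_edges") <- band_edges
  attr(out, "epoch_len") <- es$epoch_len
  out
}

#' Relative EEG power spectra by vigilance state
#'
#' Mean per-state PSD with the normalization used for cross-state spectral
#' comparison: after averaging within states, all states are jointly divided
#' by the single greatest bin value and scaled to percent, so the global
#' maximum over states and bins is exactly 100.
#'
#' @param features an [epoch_features()] table (carrying its PSD attribute)
#' @param hyp a [hypnogram()] (or plain label vector) aligned with `features`
#' @param resolution `"1hz"` (default) or `"native"` (requires
#'   `keep_native = TRUE` in [epoch_features()])
#' @param states states to include; states with zero epochs are dropped with
#'   a message
#' @return data.frame with columns `state`, `freq`, `relative_power`
#'   (percent), `n_epochs`
#' @export
relative_power_by_state <- function(features, hyp,
                                    resolution = c("1hz", "native"),
                                    states = VIGILANCE_STATES) {
  resolution <- match.arg(resolution)
  P <- attr(features, if (resolution == "1hz") "psd_1hz" else "psd_native")
  if (is.null(P)) stop("features table lacks the requested PSD attribute")
  labels <- as.character(hyp)
  if (length(labels) != ncol(P)) stop("features and hypnogram are not aligned")
  freq <- if (resolution == "1hz") as.numeric(rownames(P)) else attr(P, "freq")
  present <- states[states %in% labels]
  absent <- setdiff(states, present)
  if (length(absent)) {
    message("states with zero epochs excluded: ", paste(absent, collapse = ", "))
  }
  if (!length(present)) stop("no epochs in any requested state")
  means <- vapply(present, function(s) {
    rowMeans(P[, labels == s, drop = FALSE])
  }, numeric(nrow(P)))
  top <- max(means)
  if (top <= 0) stop("all-zero spectra; relative power undefined")
  means <- means / top * 100
  data.frame(
    state = rep(present, each = nrow(P)),
    freq = rep(freq, length(present)),
    relative_power = as.vector(means),
    n_epochs = rep(vapply(present, function(s) sum(labels == s), 0L),
                   each = nrow(P))
  )
}
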