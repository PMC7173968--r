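#' Scoring reference thresholds
#'
#' Container for the thresholds the epoch classifier needs: the EMG-integral
#' wake threshold (at or above which an epoch is muscle-active), the atonia
#' threshold (below which an epoch counts as atonic), the NREM delta-power
#' reference used by the DT-sleep rule ("at least 60-80 percent of the delta
#' power found in NREM sleep"; default ratio 0.6, the permissive end of the
#' range), a REM theta-power reference, and the structural minima: 10 epochs
#' (40 s) of antecedent wake and 3 epochs (12 s, the smallest multiple of the
#' 4-s grid exceeding 10 s) of cataplexy.
#'
#' @param emg_wake_thresh,emg_atonia_thresh microvolt-seconds
#' @param nrem_delta_ref central delta power of NREM epochs (microvolts
#'   squared)
#' @param r_theta_ref central theta power of REM epochs
#' @param theta_thresh theta-fraction threshold for REM/cataplexy (default
#'   0.5)
#' @param dt_delta_ratio,dt_theta_ratio DT-sleep power criteria relative to
#'   `nrem_delta_ref` / `r_theta_ref`
#' @param min_wake_epochs,min_cataplexy_epochs structural minima (epochs)
#' @return object of class `scoring_references`
#' @export
scoring_references <- function(emg_wake_thresh, emg_atonia_thresh,
                               nrem_delta_ref = NA_real_,
                               r_theta_ref = NA_real_,
                               theta_thresh = 0.5,
                               dt_delta_ratio = 0.6, dt_theta_ratio = 0.6,
                               min_wake_epochs = 10L,
                               min_cataplexy_epochs = 3L) {
  if (!(emg_atonia_thresh > 0 && emg_atonia_thresh <= emg_wake_thresh)) {
    stop("need 0 < emg_atonia_thresh <= emg_wake_thresh")
  }
  if (!(dt_delta_ratio > 0 && dt_delta_ratio <= 1)) {
    stop("dt_delta_ratio must be in (0, 1]")
  }
  structure(list(emg_wake_thresh = emg_wake_thresh,
                 emg_atonia_thresh = emg_atonia_thresh,
                 nrem_delta_ref = nrem_delta_ref,
                 r_theta_ref = r_theta_ref,
                 theta_thresh = theta_thresh,
                 dt_delta_ratio = dt_delta_ratio,
                 dt_theta_ratio = dt_theta_ratio,
                 min_wake_epochs = as.integer(min_wake_epochs),
                 min_cataplexy_epochs = as.integer(min_cataplexy_epochs)),
            class = "scoring_references")
}

#' @export
print.scoring_references <- function(x, ...) {
  cat(sprintf(paste0("<scoring_references> wake>=%.3g uVs, atonia<%.3g uVs, ",
                     "NR delta ref %.3g uV^2, R theta ref %.3g uV^2\n"),
              x$emg_wake_thresh, x$emg_atonia_thresh, x$nrem_delta_ref,
              x$r_theta_ref))
  invisible(x)
}

#' Estimate scoring references from a feature table
#'
#' EMG thresholds come from two-class clustering of log EMG integrals
#' (deterministic 1-D k-means initialised at the 25th/75th percentiles): the
#' wake threshold is the midpoint of the cluster centers (geometric midpoint
#' on the raw scale), the atonia threshold the 90th percentile of the
#' low-cluster members. Provisional NREM epochs are low-EMG, delta-dominant
#' epochs; their median delta power is the NREM delta reference. The REM theta
#' reference is the median theta power of low-EMG theta-dominant epochs
#' (falling back to provisional NREM epochs when no epoch is theta-dominant).
#'
#' @param features an [epoch_features()] table with at least 500 epochs
#' @param atonia_quantile quantile of the low cluster used for the atonia
#'   threshold
#' @param min_separation minimum ratio of cluster centers (raw scale) below
#'   which the EMG distribution is declared unimodal (no sleep present) and
#'   estimation fails, advising manual thresholds
#' @param ... overrides passed to [scoring_references()] (e.g.
#'   `dt_delta_ratio = 0.8`)
#' @return a [scoring_references()]
#' @export
estimate_references <- function(features, atonia_quantile = 0.9,
                                min_separation = 4, ...) {
  if (nrow(features) < 500) {
    stop("need at least 500 epochs to estimate references (got ",
         nrow(features), ")")
  }
  emg <- features$emg_integral
  if (any(!is.finite(emg)) || any(emg <= 0)) {
    stop("EMG integrals must be finite and positive for threshold estimation")
  }
  le <- log(emg)
  q <- stats::quantile(le, c(0.25, 0.75), names = FALSE)
  if (diff(q) < 1e-9) {
    stop("EMG integral distribution appears unimodal (no sleep/wake contrast);",
         " supply thresholds manually via scoring_references()")
  }
  km <- stats::kmeans(matrix(le, ncol = 1), centers = matrix(q, ncol = 1))
  lo <- which.min(km$centers)
  if (exp(abs(diff(range(km$centers)))) < min_separation) {
    stop("EMG integral distribution appears unimodal (cluster centers ",
         sprintf("%.3g and %.3g uVs", exp(min(km$centers)), exp(max(km$centers))),
         "); supply thresholds manually via scoring_references()")
  }
  wake_thresh <- exp(mean(km$centers))
  atonia_thresh <- exp(stats::quantile(le[km$cluster == lo], atonia_quantile,
                                       names = FALSE))
  bands <- c("delta", "theta", "alpha", "beta")
  dominant <- bands[max.col(as.matrix(features[, bands]))]
  low <- emg < wake_thresh
  prov_nr <- low & dominant == "delta"
  if (!any(prov_nr)) {
    stop("no provisional NREM epochs (low EMG, delta-dominant); ",
         "cannot estimate the NREM delta reference")
  }
  prov_r <- low & features$theta_fraction > 0.5
  r_theta <- if (any(prov_r, na.rm = TRUE)) {
    stats::median(features$theta[which(prov_r)])
  } else {
    stats::median(features$theta[prov_nr])
  }
  scoring_references(emg_wake_thresh = wake_thresh,
                     emg_atonia_thresh = atonia_thresh,
                     nrem_delta_ref = stats::median(features$delta[prov_nr]),
                     r_theta_ref = r_theta, ...)
}

#' Base three-state epoch classification
#'
#' The context-free rules: an epoch is wake when its EMG integral is at or
#' above the wake threshold (regardless of spectrum); otherwise REM when over
#' half its EEG power is theta; otherwise NREM (low EMG, delta-weighted EEG).
#' Epochs with missing features are flagged unscorable (`NA`).
#'
#' @param features an [epoch_features()] table
#' @param refs a [scoring_references()]
#' @return character vector of provisional labels in `{W, NR, R}` (or `NA`)
#' @export
classify_base <- function(features, refs) {
  lab <- ifelse(features$emg_integral >= refs$emg_wake_thresh, "W",
                ifelse(features$theta_fraction > refs$theta_thresh, "R", "NR"))
  lab[!is.finite(features$emg_integral) | is.na(features$theta_fraction)] <-
    NA_character_
  lab
}

#' Relabel cataplexy bouts
#'
#' Cataplexy: muscle atonia lasting more than 10 s (at least 3 consecutive
#' 4-s epochs) after more than 40 s (10 epochs) of wakefulness, with
#' theta-dominant (over 50 percent theta), low-amplitude EEG. Any maximal run
#' of non-wake epochs that are atonic and theta-dominant, of sufficient
#' length and immediately preceded by the required consecutive wake epochs,
#' is relabeled `C` in full.
#'
#' @param labels provisional labels from [classify_base()]
#' @param features an [epoch_features()] table
#' @param refs a [scoring_references()]
#' @return labels with cataplexy runs set to `"C"`
#' @export
detect_cataplexy <- function(labels, features, refs) {
  cand <- !is.na(labels) & labels != "W" &
    features$emg_integral < refs$emg_atonia_thresh &
    !is.na(features$theta_fraction) &
    features$theta_fraction > refs$theta_thresh
  rr <- runs_of(cand)
  for (i in seq_len(nrow(rr))) {
    s <- rr$start[i]; e <- rr$end[i]
    if (e - s + 1L < refs$min_cataplexy_epochs) next
    if (s <= refs$min_wake_epochs) next
    pre <- labels[(s - refs$min_wake_epochs):(s - 1L)]
    if (all(!is.na(pre) & pre == "W")) labels[s:e] <- "C"
  }
  labels
}

#' Relabel DT-sleep bouts
#'
#' DT sleep: a behavioral arrest (operationalized as EMG atonia) preceded by
#' at least 40 s (10 epochs) of wakefulness, with simultaneously high delta
#' power (at least `dt_delta_ratio` of the NREM delta reference) and high
#' theta power (at least `dt_theta_ratio` of the REM theta reference), and
#' terminated by a return to wakefulness. Cataplexy takes precedence: runs
#' already labeled `C` are never relabeled. A qualifying run cut off by the
#' end of the recording has no return to wakefulness and is left unlabeled
#' (flagged in attribute `"dt_flagged_end"`).
#'
#' @inheritParams detect_cataplexy
#' @return labels with DT-sleep runs set to `"D"`
#' @export
detect_dt_sleep <- function(labels, features, refs) {
  if (!is.finite(refs$nrem_delta_ref)) {
    stop("nrem_delta_ref is missing: cannot evaluate the DT-sleep delta ",
         "criterion")
  }
  theta_ref <- refs$r_theta_ref
  if (!is.finite(theta_ref)) {
    stop("r_theta_ref is missing: cannot evaluate the DT-sleep theta criterion")
  }
  cand <- !is.na(labels) & !labels %in% c("W", "C") &
    features$emg_integral < refs$emg_atonia_thresh &
    features$delta >= refs$dt_delta_ratio * refs$nrem_delta_ref &
    features$theta >= refs$dt_theta_ratio * theta_ref
  rr <- runs_of(cand)
  flagged <- integer(0)
  n <- length(labels)
  for (i in seq_len(nrow(rr))) {
    s <- rr$start[i]; e <- rr$end[i]
    if (s <= refs$min_wake_epochs) next
    pre <- labels[(s - refs$min_wake_epochs):(s - 1L)]
    if (!all(!is.na(pre) & pre == "W")) next
    if (e >= n) { # no following epoch: criterion (5) cannot be verified
      flagged <- c(flagged, s)
      next
    }
    if (is.na(labels[e + 1L]) || labels[e + 1L] != "W") next
    labels[s:e] <- "D"
  }
  attr(labels, "dt_flagged_end") <- flagged
  labels
}

#' Score a recording end-to-end
#'
#' Full pipeline: zero-phase band-pass filtering (EEG 1.5-30 Hz; EMG 15-300 Hz
#' capped at Nyquist), 4-s epoch segmentation, spectral features, reference
#' estimation, base W/NR/R classification, then the contextual cataplexy and
#' DT-sleep detectors. The returned hypnogram carries the references and a
#' run log (effective filter bands, dropped samples, thresholds).
#'
#' @param rec a [recording()]
#' @param overrides named list passed to [estimate_references()] /
#'   [scoring_references()] (e.g. `list(dt_delta_ratio = 0.8)`)
#' @param epoch_len epoch length (s)
#' @param band_edges see [default_band_edges()]
#' @param total_range theta-fraction denominator range (Hz)
#' @param context apply the cataplexy/DT detectors (`FALSE` = base rules only)
#' @param eeg_band,emg_band acquisition filter bands (Hz)
#' @return a [hypnogram()]; attribute `"features"` holds the feature table,
#'   attribute `"log"` the run log
#' @export
score_recording <- function(rec, overrides = list(), epoch_len = 4,
                            band_edges = default_band_edges(),
                            total_range = c(1, 31), context = TRUE,
                            eeg_band = c(1.5, 30), emg_band = c(15, 300)) {
  eeg_f <- bandpass(rec$eeg, rec$fs, eeg_band[1], eeg_band[2])
  emg_f <- bandpass(rec$emg, rec$fs, emg_band[1], emg_band[2])
  fr <- recording(eeg_f, emg_f, rec$fs, start_clock = rec$start_clock,
                  lights_on = rec$lights_on, lights_off = rec$lights_off)
  es <- epoch_segment(fr, epoch_len)
  feats <- epoch_features(es, band_edges = band_edges,
                          total_range = total_range)
  refs <- do.call(estimate_references, c(list(feats), overrides))
  labels <- classify_base(feats, refs)
  flagged <- integer(0)
  if (context) {
    labels <- detect_cataplexy(labels, feats, refs)
    labels <- detect_dt_sleep(labels, feats, refs)
    flagged <- attr(labels, "dt_flagged_end")
  }
  hyp <- hypnogram(as.character(labels), epoch_len = epoch_len,
                   start_clock = rec$start_clock,
                   lights_on = rec$lights_on, lights_off = rec$lights_off,
                   provenance = "auto", references = refs)
  attr(hyp, "features") <- feats
  attr(hyp, "log") <- list(
    eeg_band = attr(eeg_f, "effective_band"),
    emg_band = attr(emg_f, "effective_band"),
    dropped_samples = es$dropped_samples,
    emg_wake_thresh = refs$emg_wake_thresh,
    emg_atonia_thresh = refs$emg_atonia_thresh,
    nrem_delta_ref = refs$nrem_delta_ref,
    r_theta_ref = refs$r_theta_ref,
    dt_runs_flagged_at_end = flagged
  )
  hyp
}

#' Compare a scored hypnogram with ground truth
#'
#' @param pred a [hypnogram()] (or label vector)
#' @param truth a ground-truth object from [simulate_hypnogram()], a
#'   [hypnogram()], or a label vector of equal length
#' @return list with the 5x5 `confusion` matrix (rows = truth), per-state
#'   `recall` and `precision`, and overall `accuracy`
#' @export
evaluate_scoring <- function(pred, truth) {
  if (inherits(truth, "ground_truth")) truth <- truth$hypnogram
  p <- as.character(pred); t <- as.character(truth)
  if (length(p) != length(t)) {
    stop("prediction and truth differ in length (", length(p), " vs ",
         length(t), ")")
  }
  f <- function(x) factor(x, levels = VIGILANCE_STATES)
  confusion <- table(truth = f(t), pred = f(p))
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  list(confusion = unclass(confusion), recall = recall, precision = precision,
       accuracy = sum(diag(confusion)) / sum(confusion))
}

#' Check hypnogram structural invariants
#'
#' Verifies, for a label sequence, that every cataplexy run is at least
#' `min_cataplexy_epochs` long, every cataplexy or DT run is immediately
#' preceded by at least `min_wake_epochs` consecutive wake epochs, and every
#' DT run is immediately followed by wake (or ends the recording, which is
#' reported).
#'
#' @param labels a [hypnogram()] or label vector
#' @param min_wake_epochs,min_cataplexy_epochs structural minima
#' @return `TRUE` if all invariants hold, otherwise `FALSE` with attribute
#'   `"violations"` describing each failure
#' @export
audit_structure <- function(labels, min_wake_epochs = 10L,
                            min_cataplexy_epochs = 3L) {
  x <- as.character(labels)
  viol <- character(0)
  for (st in c("C", "D")) {
    rr <- runs_of(!is.na(x) & x == st)
    for (i in seq_len(nrow(rr))) {
      s <- rr$start[i]; e <- rr$end[i]
      if (st == "C" && e - s + 1L < min_cataplexy_epochs) {
        viol <- c(viol, sprintf("C run at epoch %d shorter than %d epochs",
                                s - 1L, min_cataplexy_epochs))
      }
      if (s <= min_wake_epochs ||
          !all(x[(s - min_wake_epochs):(s - 1L)] == "W", na.rm = FALSE)) {
        viol <- c(viol, sprintf("%s run at epoch %d lacks %d antecedent W epochs",
                                st, s - 1L, min_wake_epochs))
      }
      if (st == "D" && e < length(x) && (is.na(x[e + 1L]) || x[e + 1L] != "W")) {
        viol <- c(viol, sprintf("D run ending at epoch %d not followed by W",
                                e - 1L))
      }
    }
  }
  ok <- length(viol) == 0
  attr(ok, "violations") <- viol
  ok
}
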