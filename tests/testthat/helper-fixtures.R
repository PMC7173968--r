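# Shared fixtures: toy feature tables with known thresholds, a brute-force
# reference implementation of the contextual relabeling rules, and small
# synthetic recordings built through the generator.

toy_refs <- function(...) {
  scoring_references(emg_wake_thresh = 10, emg_atonia_thresh = 5,
                     nrem_delta_ref = 100, r_theta_ref = 100, ...)
}

make_features <- function(emg, delta, theta, alpha = NULL, beta = NULL) {
  n <- length(emg)
  alpha <- alpha %||% rep(1, n)
  beta <- beta %||% rep(1, n)
  tot <- delta + theta + alpha + beta
  data.frame(epoch_index = seq_len(n) - 1L, clock = 0L, phase = "dark",
             delta = delta, theta = theta, alpha = alpha, beta = beta,
             frac_delta = delta / tot, frac_theta = theta / tot,
             frac_alpha = alpha / tot, frac_beta = beta / tot,
             theta_fraction = theta / tot, emg_integral = emg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_toy_table <- function(n, seed) {
  set.seed(seed)
  make_features(emg = sample(c(1, 8, 20), n, replace = TRUE),
                delta = sample(c(30, 70, 120), n, replace = TRUE),
                theta = sample(c(30, 80, 120), n, replace = TRUE))
}

# Independent oracle: exhaustive interval scan applying the written rules,
# no shared run-finding code with the implementation.
brute_force_relabel <- function(labels, features, refs) {
  n <- length(labels)
  out <- labels
  sat_c <- labels != "W" &
    features$emg_integral < refs$emg_atonia_thresh &
    features$theta_fraction > refs$theta_thresh
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(sat_c[i:j])) next
      if (i > 1 && sat_c[i - 1]) next
      if (j < n && sat_c[j + 1]) next
      if (j - i + 1 < refs$min_cataplexy_epochs) next
      if (i <= refs$min_wake_epochs) next
      if (!all(labels[(i - refs$min_wake_epochs):(i - 1)] == "W")) next
      out[i:j] <- "C"
    }
  }
  mid <- out
  sat_d <- !mid %in% c("W", "C") &
    features$emg_integral < refs$emg_atonia_thresh &
    features$delta >= refs$dt_delta_ratio * refs$nrem_delta_ref &
    features$theta >= refs$dt_theta_ratio * refs$r_theta_ref
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(sat_d[i:j])) next
      if (i > 1 && sat_d[i - 1]) next
      if (j < n && sat_d[j + 1]) next
      if (i <= refs$min_wake_epochs) next
      if (!all(mid[(i - refs$min_wake_epochs):(i - 1)] == "W")) next
      if (j >= n || mid[j + 1] != "W") next
      out[i:j] <- "D"
    }
  }
  out
}

# Ground truth with handwritten labels but generator-driven signals.
manual_truth <- function(labels, duration = length(labels) * 4, seed = 42,
                         condition = "OXMC_ablated") {
  cfg <- preset_config(condition, "dark", duration = duration, seed = seed)
  structure(list(hypnogram = hypnogram(labels, epoch_len = cfg$epoch_len,
                                       start_clock = cfg$start_clock,
                                       lights_on = cfg$lights_on,
                                       lights_off = cfg$lights_off,
                                       provenance = "truth"),
                 config = cfg, signal_seed = seed),
            class = "ground_truth")
}

pipeline_features <- function(rec, epoch_len = 4) {
  es <- epoch_segment(recording(bandpass(rec$eeg, rec$fs, 1.5, 30),
                                bandpass(rec$emg, rec$fs, 15, 300),
                                rec$fs, rec$start_clock, rec$lights_on,
                                rec$lights_off), epoch_len)
  epoch_features(es)
}

# Config in which DT sleep shares the NREM profile exactly (the spectral null
# against the NREM-to-REM transition state), with enough REM pressure that
# half-hour recordings contain transitions.
null_dt_config <- function(seed, duration = 1800) {
  prof <- dtsleep:::preset_profiles()
  prof$D <- prof$NR
  prof$D$state <- "D"
  sim_config(prof, list(NR = c(count = 240, dwell_s = 30),
                        R = c(count = 120, dwell_s = 20),
                        D = c(count = 200, dwell_s = 14.4)),
             duration = duration, seed = seed)
}

simulate_features_pair <- function(cfg) {
  truth <- simulate_hypnogram(cfg)
  rec <- synthesize_signals(truth)
  list(features = pipeline_features(rec), hypnogram = truth$hypnogram)
}

# One scored 12-h double-ablated recording, cached across test files.
scored_oxmc_12h <- local({
  cache <- new.env()
  function(seed = 0) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      truth <- simulate_hypnogram(preset_config("OXMC_ablated", "dark",
                                                seed = seed))
      rec <- synthesize_signals(truth)
      cache[[key]] <- list(truth = truth, hyp = score_recording(rec))
    }
    cache[[key]]
  }
})
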