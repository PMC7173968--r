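#' Per-state signal profile for the synthetic generator
#'
#' Describes one vigilance state's EEG band amplitudes (standard deviation,
#' in microvolts, of the band-limited noise component per band), EMG tone
#' (mean rectified amplitude) with an epoch-to-epoch coefficient of variation,
#' and the bout-duration (dwell) distribution: a gamma of fixed shape with the
#' given mean, rounded to whole epochs and truncated below at
#' `dwell_min_epochs`.
#'
#' @param state one of `r paste(VIGILANCE_STATES, collapse = ", ")`
#' @param band_amplitudes named numeric vector (delta/theta/alpha/beta), >= 0
#' @param emg_tone mean rectified EMG amplitude (microvolts), >= 0
#' @param emg_cv epoch-level coefficient of variation of the EMG envelope
#' @param dwell_mean mean bout duration (seconds)
#' @param dwell_shape gamma shape (default 2: positive, right-skewed)
#' @param dwell_min_epochs lower truncation (epochs); cataplexy uses 3 so
#'   every generated bout satisfies the "more than 10 s" rule on the 4-s grid
#' @return object of class `state_profile`
#' @export
state_profile <- function(state, band_amplitudes, emg_tone, emg_cv = 0.3,
                          dwell_mean = 60, dwell_shape = 2,
                          dwell_min_epochs = 1L) {
  state <- match.arg(state, VIGILANCE_STATES)
  need <- c("delta", "theta", "alpha", "beta")
  if (!all(need %in% names(band_amplitudes))) {
    stop("band_amplitudes must name ", paste(need, collapse = ", "))
  }
  if (any(band_amplitudes < 0) || emg_tone < 0) {
    stop("band amplitudes and emg_tone must be non-negative")
  }
  if (dwell_mean <= 0) stop("dwell_mean must be positive")
  structure(list(state = state,
                 band_amplitudes = band_amplitudes[need],
                 emg_tone = emg_tone, emg_cv = emg_cv,
                 dwell_mean = dwell_mean, dwell_shape = dwell_shape,
                 dwell_min_epochs = as.integer(dwell_min_epochs)),
            class = "state_profile")
}

# Mean of max(min_ep, round(X)) for X ~ gamma(shape, mean = m) in epochs.
dwell_realized_mean <- function(m, shape, min_ep) {
  sc <- m / shape
  k_hi <- max(min_ep + 5L, ceiling(stats::qgamma(1 - 1e-12, shape, scale = sc)))
  ks <- min_ep:k_hi
  p_hi <- stats::pgamma(ks + 0.5, shape, scale = sc)
  p_lo <- stats::pgamma(ks - 0.5, shape, scale = sc)
  probs <- p_hi - p_lo
  probs[1] <- p_hi[1] # everything below min_ep + 0.5 is pinned at min_ep
  sum(ks * probs) + (k_hi + 1) * (1 - p_hi[length(ks)])
}

# Gamma mean (epochs) whose rounded, truncated dwell has the target mean.
calibrate_dwell <- function(target_ep, shape, min_ep) {
  if (target_ep < min_ep) {
    stop("target dwell mean (", target_ep, " epochs) below the minimum of ",
         min_ep, " epochs")
  }
  if (target_ep == min_ep) return(1e-6)
  stats::uniroot(function(m) dwell_realized_mean(m, shape, min_ep) - target_ep,
                 lower = 1e-6, upper = 4 * target_ep + 4, tol = 1e-10)$root
}

#' Build a calibrated simulation configuration
#'
#' Defines a semi-Markov generator over the five vigilance states. Bout
#' targets give, for each non-wake state, the expected number of bouts per
#' 12 h and the mean bout duration; wake fills the remaining time. Transition
#' weights are solved in closed form so the long-run expected bout counts
#' match the targets: REM is entered only from NREM; cataplexy and DT sleep
#' are entered only from wake bouts that have lasted at least
#' `min_wake_before_C_or_D` epochs (so the antecedent-wake requirement holds
#' by construction); DT sleep always exits to wake.
#'
#' @param profiles named list of [state_profile()]s, one per state in
#'   `W, NR, R` plus optionally `C`, `D`
#' @param targets named list for the non-wake states, each
#'   `c(count = bouts per 12 h, dwell_s = mean bout seconds)`; omit a state
#'   (or give `count = 0`) to exclude it
#' @param duration recording length (s)
#' @param fs sampling rate (Hz)
#' @param epoch_len epoch length (s)
#' @param start_clock clock time of the first sample
#' @param lights_on,lights_off light schedule
#' @param min_wake_before_C_or_D antecedent-wake requirement (epochs)
#' @param seed integer seed; one RNG stream per recording, split
#'   deterministically between hypnogram and signal synthesis
#' @return object of class `sim_config`
#' @export
sim_config <- function(profiles, targets, duration = 43200, fs = 128,
                       epoch_len = 4, start_clock = "20:00",
                       lights_on = "08:00", lights_off = "20:00",
                       min_wake_before_C_or_D = 10L, seed = 0L) {
  if (epoch_len * fs != round(epoch_len * fs)) {
    stop("epoch_len * fs must be an integer")
  }
  if (duration <= 0 || duration %% epoch_len != 0) {
    stop("duration must be a positive multiple of epoch_len")
  }
  if (min_wake_before_C_or_D * epoch_len < 40) {
    stop("min_wake_before_C_or_D * epoch_len must cover 40 s of wakefulness")
  }
  ref_s <- 43200 # bout counts are expressed per 12 h
  cnt <- function(s) if (!is.null(targets[[s]])) unname(targets[[s]]["count"]) else 0
  dws <- function(s) if (!is.null(targets[[s]])) unname(targets[[s]]["dwell_s"]) else NA
  n_nr <- cnt("NR"); n_r <- cnt("R"); n_c <- cnt("C"); n_d <- cnt("D")
  if (n_nr <= 0) stop("targets must include NR with a positive count")
  if (n_r > n_nr) stop("R bout count cannot exceed NR bout count (R is entered from NR)")
  states <- c("W", "NR", if (n_r > 0) "R", if (n_c > 0) "C", if (n_d > 0) "D")
  for (s in states) {
    if (is.null(profiles[[s]])) stop("missing profile for state ", s)
  }
  for (s in c("C", "D")) {
    if (s %in% states && profiles[[s]]$emg_tone >= profiles$W$emg_tone) {
      stop(s, " profile must have lower EMG tone than W")
    }
  }
  nonw_s <- sum(vapply(c("NR", "R", "C", "D"),
                       function(s) cnt(s) * (if (cnt(s) > 0) dws(s) else 0), 0))
  w_total <- ref_s - nonw_s
  if (w_total <= 0) stop("bout targets exceed the 12-h budget")
  n_w <- n_nr + n_c + n_d
  d_w_s <- w_total / n_w

  dwell_s <- c(W = d_w_s, NR = dws("NR"),
               R = if (n_r > 0) dws("R") else NA,
               C = if (n_c > 0) dws("C") else NA,
               D = if (n_d > 0) dws("D") else NA)
  profiles$W$dwell_mean <- d_w_s
  for (s in c("NR", "R", "C", "D")) {
    if (s %in% states) profiles[[s]]$dwell_mean <- dwell_s[[s]]
  }
  gamma_mean_ep <- sapply(VIGILANCE_STATES, function(s) {
    if (!s %in% states) return(NA_real_)
    p <- profiles[[s]]
    calibrate_dwell(dwell_s[[s]] / epoch_len, p$dwell_shape, p$dwell_min_epochs)
  })

  # P(wake bout >= min_wake epochs): round(X) >= k  <=>  X >= k - 0.5
  q <- 1 - stats::pgamma(min_wake_before_C_or_D - 0.5, profiles$W$dwell_shape,
                         scale = gamma_mean_ep["W"] / profiles$W$dwell_shape)
  p_wc <- n_c / (q * n_w)
  p_wd <- n_d / (q * n_w)
  if (p_wc + p_wd > 1) {
    stop("cataplexy/DT bout targets unreachable: too few wake bouts reach ",
         min_wake_before_C_or_D, " epochs")
  }
  tw <- matrix(0, 5, 5, dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES))
  tw["W", "NR"] <- 1 - p_wc - p_wd
  tw["W", "C"] <- p_wc
  tw["W", "D"] <- p_wd
  tw["NR", "R"] <- n_r / n_nr
  tw["NR", "W"] <- 1 - n_r / n_nr
  tw["R", "W"] <- 1
  tw["C", "W"] <- 1
  tw["D", "W"] <- 1 # DT sleep is terminated by a return to wakefulness

  cfg <- structure(list(
    profiles = profiles, transition_weights = tw,
    duration = duration, fs = fs, epoch_len = epoch_len,
    start_clock = parse_clock(start_clock),
    lights_on = parse_clock(lights_on), lights_off = parse_clock(lights_off),
    min_wake_before_C_or_D = as.integer(min_wake_before_C_or_D),
    seed = as.integer(seed), states = states, targets = targets,
    gamma_mean_ep = gamma_mean_ep, wake_eligible_prob = q
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration's structural invariants
#'
#' Checks that transitions into cataplexy and DT sleep originate only from
#' wake, that DT sleep exits only to wake, that self-transitions carry zero
#' weight (dwell times come from the dwell distributions), and that the
#' antecedent-wake requirement is expressible on the epoch grid.
#'
#' @param cfg a [sim_config()]
#' @return `cfg`, invisibly; errors on violation
#' @export
validate_sim_config <- function(cfg) {
  tw <- cfg$transition_weights
  if (any(diag(tw) != 0)) stop("self-transitions must have zero weight")
  if (any(tw[setdiff(VIGILANCE_STATES, "W"), c("C", "D")] != 0)) {
    stop("C and D may only be entered from W")
  }
  if (any(tw["D", setdiff(VIGILANCE_STATES, "W")] != 0)) {
    stop("D may only exit to W")
  }
  if (any(tw < 0)) stop("transition weights must be non-negative")
  if (cfg$min_wake_before_C_or_D * cfg$epoch_len < 40) {
    stop("antecedent-wake requirement must cover 40 s")
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Presets: study conditions for the three genotypes. Per-phase totals and
# cataplexy/DT statistics follow the published 4-week group means (total
# state times, cataplexy counts and durations per phase; DT 98.3 bouts of
# 14.4 s mean in the dark phase). NREM/REM mean bout durations and the
# light-phase DT bout count are not published and are fixed at realistic
# values (see the methods vignette).

preset_profiles <- function() {
  list(
    W = state_profile("W", c(delta = 15, theta = 15, alpha = 12, beta = 12),
                      emg_tone = 25, emg_cv = 0.2),
    NR = state_profile("NR", c(delta = 60, theta = 18, alpha = 9, beta = 6),
                       emg_tone = 2.5, emg_cv = 0.3),
    R = state_profile("R", c(delta = 15, theta = 55, alpha = 9, beta = 6),
                      emg_tone = 1, emg_cv = 0.3),
    C = state_profile("C", c(delta = 15, theta = 55, alpha = 9, beta = 6),
                      emg_tone = 1, emg_cv = 0.3, dwell_min_epochs = 3L),
    D = state_profile("D", c(delta = 110, theta = 70, alpha = 9, beta = 6),
                      emg_tone = 1, emg_cv = 0.3)
  )
}

preset_targets <- function(condition, phase) {
  t <- switch(condition,
    intact = switch(phase,
      dark = list(NR = c(count = 220 * 60 / 90, dwell_s = 90),
                  R = c(count = 30 * 60 / 65, dwell_s = 65)),
      light = list(NR = c(count = 390 * 60 / 100, dwell_s = 100),
                   R = c(count = 55 * 60 / 70, dwell_s = 70))),
    OX_ablated = switch(phase,
      dark = list(NR = c(count = 258.3 * 60 / 60, dwell_s = 60),
                  R = c(count = 25.6 * 60 / 60, dwell_s = 60),
                  C = c(count = 14.8, dwell_s = 53.3)),
      light = list(NR = c(count = 389.8 * 60 / 90, dwell_s = 90),
                   R = c(count = 46.3 * 60 / 60, dwell_s = 60),
                   C = c(count = 8.3, dwell_s = 50.0))),
    OXMC_ablated = switch(phase,
      dark = list(NR = c(count = 90.5 * 60 / 60, dwell_s = 60),
                  R = c(count = 2.7 * 60 / 60, dwell_s = 60),
                  C = c(count = 16.9, dwell_s = 113.0),
                  D = c(count = 98.3, dwell_s = 14.4)),
      light = list(NR = c(count = 340.1 * 60 / 90, dwell_s = 90),
                   R = c(count = 20.8 * 60 / 60, dwell_s = 60),
                   C = c(count = 15.4, dwell_s = 96.3),
                   D = c(count = 40, dwell_s = 14.4)))
  )
  t
}

#' Preset simulation configurations for the three study conditions
#'
#' `intact`: neither cataplexy nor DT sleep (all transition weights into C and
#' D are zero). `OX_ablated` (orexin-neuron ablated): cataplexy but no DT
#' sleep (dark phase: 14.8 bouts of 53.3 s mean per 12 h). `OXMC_ablated`
#' (dual orexin + MCH ablated): cataplexy (dark: 16.9 bouts, 113.0 s mean)
#' and DT sleep (dark: 98.3 bouts, 14.4 s mean). Phase emphasis selects which
#' phase's architecture the dynamics embody and sets the recording start at
#' that phase's onset (dark 20:00, light 08:00).
#'
#' @param condition `"intact"`, `"OX_ablated"` or `"OXMC_ablated"`
#' @param phase_emphasis `"dark"` or `"light"`
#' @param duration recording length (s), default one 12-h phase
#' @param seed integer seed
#' @param ... further arguments to [sim_config()]
#' @return a [sim_config()]
#' @export
preset_config <- function(condition = c("intact", "OX_ablated", "OXMC_ablated"),
                          phase_emphasis = c("dark", "light"),
                          duration = 43200, seed = 0L, ...) {
  condition <- match.arg(condition)
  phase_emphasis <- match.arg(phase_emphasis)
  targets <- preset_targets(condition, phase_emphasis)
  sim_config(preset_profiles(), targets, duration = duration,
             start_clock = if (phase_emphasis == "dark") "20:00" else "08:00",
             seed = seed, ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %g s @ %g Hz, epoch %g s, states %s, seed %d\n",
              x$duration, x$fs, x$epoch_len,
              paste(x$states, collapse = "/"), x$seed))
  for (s in x$states) {
    cat(sprintf("  %-2s dwell %.1f s, EMG %.3g uV\n", s,
                x$profiles[[s]]$dwell_mean, x$profiles[[s]]$emg_tone))
  }
  invisible(x)
}

# Split one seed into independent sub-seeds for hypnogram vs signals.
split_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::runif(2) # burn to decorrelate from trivially related seeds
  sample.int(.Machine$integer.max, 2)
}

#' Simulate a ground-truth hypnogram
#'
#' Draws alternating (state, dwell) pairs from the semi-Markov model: dwell
#' times are rounded truncated gammas per state; after a wake bout shorter
#' than the antecedent-wake requirement, transitions into cataplexy and DT
#' sleep are masked out, so every generated C/D bout is preceded by the
#' required consecutive wake epochs. A trailing C or D bout cut off by the
#' recording end is relabeled wake so the structural invariants hold
#' unconditionally. Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()]
#' @return object of class `ground_truth`: list with the true `hypnogram`
#'   (provenance `"truth"`), the `config`, and the signal-synthesis sub-seed
#' @export
simulate_hypnogram <- function(config) {
  validate_sim_config(config)
  n_ep <- config$duration / config$epoch_len
  seeds <- split_seed(config$seed)
  set.seed(seeds[1])
  tw <- config$transition_weights[config$states, config$states, drop = FALSE]
  draw_dwell <- function(s) {
    p <- config$profiles[[s]]
    x <- stats::rgamma(1, p$dwell_shape,
                       scale = config$gamma_mean_ep[s] / p$dwell_shape)
    max(p$dwell_min_epochs, round(x))
  }
  labels <- character(n_ep)
  filled <- 0L
  cur <- "W"
  while (filled < n_ep) {
    d <- draw_dwell(cur)
    take <- min(d, n_ep - filled)
    labels[(filled + 1L):(filled + take)] <- cur
    filled <- filled + take
    if (filled >= n_ep) break
    w <- tw[cur, ]
    if (cur == "W" && d < config$min_wake_before_C_or_D) {
      w[intersect(c("C", "D"), names(w))] <- 0
    }
    cur <- sample(colnames(tw), 1, prob = w)
  }
  # a C/D bout truncated by the recording end has no return to wakefulness
  last <- runs_of(labels == labels[n_ep])
  tail_run <- last[nrow(last), ]
  if (tail_run$end == n_ep && labels[n_ep] %in% c("C", "D")) {
    labels[tail_run$start:n_ep] <- "W"
  }
  hyp <- hypnogram(labels, epoch_len = config$epoch_len,
                   start_clock = config$start_clock,
                   lights_on = config$lights_on,
                   lights_off = config$lights_off,
                   provenance = "truth")
  ok <- audit_structure(hyp, config$min_wake_before_C_or_D,
                        config$profiles$C$dwell_min_epochs %||% 3L)
  if (!ok) stop("generator invariant violated: ",
                paste(attr(ok, "violations"), collapse = "; "))
  structure(list(hypnogram = hyp, config = config, signal_seed = seeds[2]),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  print(x$hypnogram)
  invisible(x)
}

# Band-limited unit-variance Gaussian noise via frequency-domain synthesis:
# complex Gaussian coefficients on the bins in [lo, hi), hermitian-symmetric,
# inverse FFT. Equivalent to ideal band-pass filtering of white noise.
bandlimited_noise <- function(n, fs, lo, hi) {
  freq <- (seq_len(n %/% 2 + 1L) - 1L) * fs / n
  pos <- which(freq >= lo & freq < hi)
  if (!length(pos)) return(numeric(n))
  z <- complex(real = stats::rnorm(length(pos)),
               imaginary = stats::rnorm(length(pos)))
  Z <- complex(length.out = n)
  Z[pos] <- z
  Z[n - pos + 2L] <- Conj(z)
  x <- Re(stats::fft(Z, inverse = TRUE))
  x / stats::sd(x)
}

# Piecewise-constant per-epoch values expanded to samples, with a raised-
# cosine crossfade of `ramp_s` seconds straddling each value change.
expand_with_crossfade <- function(vals, L, fs, ramp_s = 0.5) {
  w <- rep(vals, each = L)
  h <- round(ramp_s * fs / 2)
  if (h < 1) return(w)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(2 * h) - 0.5) / (2 * h)))
  ch <- which(diff(vals) != 0)
  for (b in ch) {
    j <- b * L
    w[(j - h + 1L):(j + h)] <- vals[b] + (vals[b + 1L] - vals[b]) * ramp
  }
  w
}

#' Synthesize EEG/EMG signals for a ground-truth hypnogram
#'
#' EEG is a sum over bands of band-limited Gaussian noise, each band scaled
#' per sample by the current state's band amplitude. EMG is white Gaussian
#' noise whose rectified-mean envelope follows the state's tone with an
#' epoch-level lognormal modulation of the configured coefficient of
#' variation. State changes are smoothed with a 0.5-s raised-cosine crossfade
#' straddling the boundary. Deterministic for a fixed config seed, and
#' independent of the hypnogram RNG stream.
#'
#' @param truth a `ground_truth` from [simulate_hypnogram()]
#' @return a [recording()]
#' @export
synthesize_signals <- function(truth) {
  cfg <- truth$config
  labels <- as.character(truth$hypnogram)
  n_ep <- length(labels)
  L <- as.integer(cfg$epoch_len * cfg$fs)
  N <- n_ep * L
  set.seed(truth$signal_seed)
  edges <- default_band_edges()
  eeg <- numeric(N)
  for (b in names(edges)) {
    amps <- vapply(cfg$profiles, function(p) p$band_amplitudes[[b]], 0)[labels]
    # each band component spans the frequency support of the integer-centered
    # 1-Hz analysis bins of that band (band [lo, hi) -> [lo-0.5, hi-0.5) Hz),
    # so a band's power is measured by its own bins, not its neighbor's
    x <- bandlimited_noise(N, cfg$fs, edges[[b]][1] - 0.5, edges[[b]][2] - 0.5)
    eeg <- eeg + expand_with_crossfade(amps, L, cfg$fs) * x
  }
  tone <- vapply(cfg$profiles, function(p) p$emg_tone, 0)[labels]
  cv <- vapply(cfg$profiles, function(p) p$emg_cv, 0)[labels]
  sdl <- sqrt(log(1 + cv^2))
  mod <- exp(stats::rnorm(n_ep, -sdl^2 / 2, sdl))
  env <- expand_with_crossfade(tone * mod, L, cfg$fs)
  emg <- env * sqrt(pi / 2) * stats::rnorm(N)
  recording(eeg, emg, cfg$fs, start_clock = cfg$start_clock,
            lights_on = cfg$lights_on, lights_off = cfg$lights_off)
}

#' Write a simulated recording, its ground truth and its configuration
#'
#' Writes the recording as EDF (signals labeled EEG/EMG, physical unit
#' microvolts), the true hypnogram as TSV, and the configuration as YAML.
#'
#' @param truth a `ground_truth`
#' @param rec the matching [synthesize_signals()] recording
#' @param edf_path,hypnogram_path,config_path output files (`NULL` = skip)
#' @return invisibly, the paths written
#' @export
write_simulation <- function(truth, rec, edf_path = NULL,
                             hypnogram_path = NULL, config_path = NULL) {
  if (!is.null(edf_path)) write_edf(rec, edf_path)
  if (!is.null(hypnogram_path)) write_hypnogram(truth$hypnogram, hypnogram_path)
  if (!is.null(config_path)) {
    cfg <- truth$config
    out <- list(
      duration = cfg$duration, fs = cfg$fs, epoch_len = cfg$epoch_len,
      start_clock = format_clock(cfg$start_clock),
      lights_on = format_clock(cfg$lights_on),
      lights_off = format_clock(cfg$lights_off),
      min_wake_before_C_or_D = cfg$min_wake_before_C_or_D,
      seed = cfg$seed,
      profiles = lapply(cfg$profiles[cfg$states], function(p) {
        list(band_amplitudes = as.list(p$band_amplitudes),
             emg_tone = p$emg_tone, emg_cv = p$emg_cv,
             dwell_dist = list(family = "gamma", shape = p$dwell_shape,
                               mean_s = p$dwell_mean,
                               min_epochs = p$dwell_min_epochs))
      }),
      transition_weights = apply(cfg$transition_weights, 1, as.list,
                                 simplify = FALSE)
    )
    yaml::write_yaml(out, config_path)
  }
  invisible(c(edf = edf_path, hypnogram = hypnogram_path,
              config = config_path))
}
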