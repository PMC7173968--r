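#' Extract bouts (maximal same-state runs) from a hypnogram
#'
#' Bouts partition the hypnogram; each bout records its phase (light/dark, by
#' the clock time of its start epoch) and the length of the immediately
#' preceding wake run (`antecedent_wake`, epochs; 0 when the previous bout is
#' not wake).
#'
#' @param hyp a [hypnogram()], or a label vector together with the metadata
#'   arguments
#' @param epoch_len,start_clock,lights_on,lights_off metadata (defaults come
#'   from the hypnogram's attributes)
#' @return data.frame of class `bout_table`: `state`, `start_epoch` (0-based),
#'   `n_epochs`, `duration_s`, `phase`, `antecedent_wake`
#' @export
extract_bouts <- function(hyp, epoch_len = attr(hyp, "epoch_len") %||% 4,
                          start_clock = attr(hyp, "start_clock") %||% 0,
                          lights_on = attr(hyp, "lights_on") %||% "08:00",
                          lights_off = attr(hyp, "lights_off") %||% "20:00") {
  x <- as.character(hyp)
  if (!length(x)) stop("empty hypnogram")
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  clock <- (parse_clock(start_clock) + (starts - 1L) * epoch_len) %% 86400L
  prev_w <- c(0L, ifelse(r$values[-length(r$values)] == "W",
                         r$lengths[-length(r$lengths)], 0L))
  out <- data.frame(
    state = r$values,
    start_epoch = starts - 1L,
    n_epochs = r$lengths,
    duration_s = r$lengths * epoch_len,
    phase = ifelse(in_light_phase(clock, lights_on, lights_off),
                   "light", "dark"),
    antecedent_wake = prev_w
  )
  attr(out, "epoch_len") <- epoch_len
  attr(out, "start_clock") <- parse_clock(start_clock)
  attr(out, "lights_on") <- parse_clock(lights_on)
  attr(out, "lights_off") <- parse_clock(lights_off)
  class(out) <- c("bout_table", "data.frame")
  out
}

#' Per-phase sleep-architecture summary
#'
#' Totals, bout counts and mean bout durations per (state, phase). Totals are
#' epoch-accurate (each epoch contributes to the phase its own clock time
#' falls in), so state totals sum exactly to each phase's recorded duration.
#' Bout counts and mean bout durations assign each bout to the phase of its
#' start epoch; the two conventions coincide unless a bout spans a light/dark
#' boundary.
#'
#' @param bouts a `bout_table` from [extract_bouts()]
#' @param epoch_len,start_clock,lights_on,lights_off metadata (defaults from
#'   the bout table's attributes)
#' @return data.frame: `state`, `phase`, `total_min`, `n_bouts`,
#'   `mean_bout_s` (`NA` where a state has no bouts in a phase)
#' @export
phase_summary <- function(bouts,
                          epoch_len = attr(bouts, "epoch_len") %||% 4,
                          start_clock = attr(bouts, "start_clock") %||% 0,
                          lights_on = attr(bouts, "lights_on") %||% "08:00",
                          lights_off = attr(bouts, "lights_off") %||% "20:00") {
  if (is.null(lights_on) || is.null(lights_off)) stop("missing light schedule")
  ep_state <- rep(bouts$state, bouts$n_epochs)
  ep_idx <- seq_along(ep_state) - 1L
  ep_clock <- (parse_clock(start_clock) + ep_idx * epoch_len) %% 86400L
  ep_phase <- ifelse(in_light_phase(ep_clock, lights_on, lights_off),
                     "light", "dark")
  phases <- unique(ep_phase)
  grid <- expand.grid(state = VIGILANCE_STATES, phase = phases,
                      stringsAsFactors = FALSE)
  grid$total_min <- mapply(function(s, p) {
    sum(ep_state == s & ep_phase == p) * epoch_len / 60
  }, grid$state, grid$phase)
  grid$n_bouts <- mapply(function(s, p) {
    sum(bouts$state == s & bouts$phase == p)
  }, grid$state, grid$phase)
  grid$mean_bout_s <- mapply(function(s, p) {
    d <- bouts$duration_s[bouts$state == s & bouts$phase == p]
    if (length(d)) mean(d) else NA_real_
  }, grid$state, grid$phase)
  grid
}

#' Fold difference between two group values
#'
#' Ratio of the second argument over the first (e.g. dual-ablated over
#' orexin-ablated group means). Accepts plain numbers, or two
#' [phase_summary()] tables plus a (metric, state, phase) selector. Full
#' precision is returned; round to 2 decimals for report output.
#'
#' @param a,b numeric values, or [phase_summary()] data.frames
#' @param metric column name (`"total_min"`, `"n_bouts"`, `"mean_bout_s"`)
#' @param state,phase row selector when summaries are given
#' @return `b / a` at full precision
#' @export
fold_difference <- function(a, b, metric = NULL, state = NULL, phase = NULL) {
  pick <- function(x) {
    if (is.numeric(x)) return(x)
    if (is.null(metric) || is.null(state) || is.null(phase)) {
      stop("metric, state and phase are required with summary tables")
    }
    v <- x[[metric]][x$state == state & x$phase == phase]
    if (!length(v) || is.na(v)) stop("metric not present for ", state, "/", phase)
    v
  }
  den <- pick(a); num <- pick(b)
  if (den == 0) stop("zero denominator in fold difference")
  num / den
}

#' Hourly architecture summary over a window
#'
#' Totals are split at hour boundaries (a bout contributes its overlap to
#' each hour); a bout spanning a boundary is counted once, in the hour of its
#' start epoch, and its full duration enters that hour's mean bout duration.
#'
#' @param bouts a `bout_table`
#' @param window_start_epoch first epoch (0-based) of the window
#' @param n_hours number of 1-h bins
#' @param epoch_len epoch length (s)
#' @return data.frame: `hour` (0-based), `state`, `total_min`, `n_bouts`,
#'   `mean_bout_s` (`NA` where no bout starts in the hour)
#' @export
hourly_summary <- function(bouts, window_start_epoch = 0L, n_hours,
                           epoch_len = attr(bouts, "epoch_len") %||% 4) {
  eph <- 3600 / epoch_len
  if (eph != round(eph)) stop("epoch_len must divide one hour")
  n_total <- sum(bouts$n_epochs)
  if (window_start_epoch < 0 ||
      window_start_epoch + n_hours * eph > n_total) {
    stop("window outside recording (", n_total, " epochs)")
  }
  ep_state <- rep(bouts$state, bouts$n_epochs)
  out <- expand.grid(hour = seq_len(n_hours) - 1L, state = VIGILANCE_STATES,
                     stringsAsFactors = FALSE)[, c("hour", "state")]
  out$total_min <- mapply(function(h, s) {
    idx <- window_start_epoch + h * eph + seq_len(eph)
    sum(ep_state[idx] == s) * epoch_len / 60
  }, out$hour, out$state)
  bout_hour <- (bouts$start_epoch - window_start_epoch) %/% eph
  in_win <- bouts$start_epoch >= window_start_epoch & bout_hour < n_hours
  out$n_bouts <- mapply(function(h, s) {
    sum(in_win & bout_hour == h & bouts$state == s)
  }, out$hour, out$state)
  out$mean_bout_s <- mapply(function(h, s) {
    d <- bouts$duration_s[in_win & bout_hour == h & bouts$state == s]
    if (length(d)) mean(d) else NA_real_
  }, out$hour, out$state)
  out[order(out$hour, match(out$state, VIGILANCE_STATES)), ]
}

#' NREM-to-REM transition windows
#'
#' The transition from NREM to REM sleep is the three epochs (12 s)
#' immediately before a REM bout. NREM runs shorter than three epochs before
#' a REM bout are skipped (counted in attribute `"skipped"`).
#'
#' @param hyp a [hypnogram()] or label vector
#' @return integer matrix, one row per transition, columns `e1,e2,e3`: the
#'   0-based indices of the last three NREM epochs before the REM bout
#' @export
nrem_to_rem_transitions <- function(hyp) {
  x <- as.character(hyp)
  out <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("e1", "e2", "e3")))
  skipped <- 0L
  if (length(x) >= 2) {
    b <- which(x[-length(x)] == "NR" & x[-1] == "R")
    for (i in b) {
      run_start <- i
      while (run_start > 1 && x[run_start - 1] == "NR") run_start <- run_start - 1
      if (i - run_start + 1L >= 3L) {
        out <- rbind(out, (i - 2L):i - 1L)
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Compare DT-sleep and NREM-to-REM transition spectra
#'
#' For each recording, averages the band fractions and EMG integral over DT
#' epochs and over transition epochs, then compares the two states per band
#' with paired t-tests across recordings. Band p-values are Bonferroni
#' adjusted (4 bands); significance should be judged on the adjusted values.
#' Recordings lacking DT epochs or transitions are excluded from the paired
#' tests (reported in `excluded`). With fewer than two usable recordings the
#' per-recording means are returned and the tests are skipped with a notice.
#'
#' @param recordings one `list(features =, hypnogram =)` pair or a list of
#'   such pairs (one per recording); features from [epoch_features()],
#'   hypnograms aligned per epoch
#' @return list: `per_recording` (means per recording and state),
#'   `tests` (per-band paired t-tests, plus the EMG integral row), `n_used`,
#'   `excluded`, `note`
#' @export
compare_dt_vs_transition <- function(recordings) {
  if (!is.null(recordings$features)) recordings <- list(recordings)
  cols <- c("frac_delta", "frac_theta", "frac_alpha", "frac_beta",
            "emg_integral")
  rows <- list(); excluded <- integer(0)
  for (i in seq_along(recordings)) {
    feats <- recordings[[i]]$features
    hyp <- as.character(recordings[[i]]$hypnogram)
    if (nrow(feats) != length(hyp)) stop("features/hypnogram misaligned in recording ", i)
    d_idx <- which(hyp == "D")
    tr <- nrem_to_rem_transitions(hyp)
    t_idx <- as.vector(t(tr)) + 1L
    if (!length(d_idx) || !length(t_idx)) {
      excluded <- c(excluded, i)
      next
    }
    m <- function(idx) colMeans(feats[idx, cols, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      recording = i,
      rbind(data.frame(group = "DT", t(m(d_idx))),
            data.frame(group = "transition", t(m(t_idx)))))
  }
  if (!length(rows)) {
    stop("no recording contains both DT epochs and NREM-to-REM transitions")
  }
  per_rec <- do.call(rbind, rows)
  n_used <- length(rows)
  tests <- NULL
  note <- NULL
  if (n_used >= 2) {
    dt <- per_rec[per_rec$group == "DT", cols, drop = FALSE]
    tr <- per_rec[per_rec$group == "transition", cols, drop = FALSE]
    tests <- do.call(rbind, lapply(cols, function(cc) {
      tt <- tryCatch(stats::t.test(dt[[cc]], tr[[cc]], paired = TRUE),
                     error = function(e) NULL)
      data.frame(measure = cc,
                 mean_dt = mean(dt[[cc]]), mean_transition = mean(tr[[cc]]),
                 statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                 p = if (is.null(tt)) NA_real_ else tt$p.value)
    }))
    is_band <- tests$measure != "emg_integral"
    tests$p_adj <- NA_real_
    tests$p_adj[is_band] <- pmin(1, tests$p[is_band] * sum(is_band))
    tests$p_adj[!is_band] <- tests$p[!is_band]
  } else {
    note <- "only one usable recording: per-state means returned, tests skipped"
    message(note)
  }
  list(per_recording = per_rec, tests = tests, n_used = n_used,
       excluded = excluded, note = note)
}

#' Group comparisons: t-tests and one-way ANOVA with Bonferroni post hoc
#'
#' `unpaired`: classical pooled-variance two-sample t-test. `paired`: paired
#' t-test (two groups of equal length). `oneway_bonferroni`: one-way ANOVA
#' followed by Bonferroni-adjusted pairwise t-tests (pooled SD).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2)
#' @param design `"unpaired"`, `"paired"` or `"oneway_bonferroni"`
#' @return for t-tests: data.frame with `statistic`, `df`, `p`, `p_adj`; for
#'   ANOVA: list with `anova` (F, df, p) and `pairwise` (raw and
#'   Bonferroni-adjusted p per pair)
#' @export
group_tests <- function(groups, design = c("unpaired", "paired",
                                           "oneway_bonferroni")) {
  design <- match.arg(design)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need at least 2 groups with n >= 2 each")
  }
  vars <- vapply(groups, stats::var, 0)
  if (all(vars == 0) && design != "paired") {
    if (length(unique(vapply(groups, function(g) g[1], 0))) == 1 &&
        length(groups) == 2) {
      return(data.frame(statistic = 0, df = sum(lengths(groups)) - 2,
                        p = 1, p_adj = 1))
    }
    stop("zero variance in all groups")
  }
  if (design == "unpaired") {
    if (length(groups) != 2) stop("unpaired design needs exactly 2 groups")
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    return(data.frame(statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value,
                      p_adj = tt$p.value))
  }
  if (design == "paired") {
    if (length(groups) != 2 || length(groups[[1]]) != length(groups[[2]])) {
      stop("paired design needs 2 groups of equal length")
    }
    d <- groups[[1]] - groups[[2]]
    if (stats::var(d) == 0) {
      if (mean(d) == 0) {
        return(data.frame(statistic = 0, df = length(d) - 1, p = 1, p_adj = 1))
      }
      stop("zero variance of paired differences with nonzero mean")
    }
    tt <- stats::t.test(groups[[1]], groups[[2]], paired = TRUE)
    return(data.frame(statistic = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value,
                      p_adj = tt$p.value))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  raw <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  m <- nrow(pairs)
  pairwise <- data.frame(
    group1 = rownames(raw)[pairs[, 1]],
    group2 = colnames(raw)[pairs[, 2]],
    p = raw[pairs],
    p_adj = pmin(1, raw[pairs] * m)
  )
  list(anova = data.frame(statistic = s$`F value`[1], df1 = s$Df[1],
                          df2 = s$Df[2], p = s$`Pr(>F)`[1]),
       pairwise = pairwise)
}
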