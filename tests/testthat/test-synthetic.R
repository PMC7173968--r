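test_that("presets encode the study conditions", {
  intact <- preset_config("intact", "dark")
  expect_true(all(intact$transition_weights[, c("C", "D")] == 0))

  oxmc <- preset_config("OXMC_ablated", "dark")
  expect_equal(oxmc$profiles$D$dwell_mean, 14.4)
  expect_equal(unname(oxmc$targets$D["count"]), 98.3)
  expect_equal(oxmc$profiles$C$dwell_mean, 113.0)
  expect_equal(unname(oxmc$targets$C["count"]), 16.9)

  ox <- preset_config("OX_ablated", "dark")
  expect_equal(ox$profiles$C$dwell_mean, 53.3)
  expect_false("D" %in% ox$states)
  expect_true(all(ox$transition_weights[, "D"] == 0))

  light <- preset_config("OXMC_ablated", "light")
  expect_equal(light$start_clock, parse_clock("08:00"))
  expect_equal(light$profiles$D$dwell_mean, 14.4)

  expect_error(preset_config("mutant"), "arg")
  expect_error(preset_config("intact", duration = 43201), "multiple")
})

test_that("profile and config validation reject inconsistent inputs", {
  expect_error(state_profile("W", c(delta = -1, theta = 1, alpha = 1, beta = 1),
                             emg_tone = 1), "non-negative")
  expect_error(state_profile("W", c(delta = 1, theta = 1), emg_tone = 1),
               "band_amplitudes")
  prof <- dtsleep:::preset_profiles()
  prof$C$emg_tone <- 30 # atonia state more active than wake
  expect_error(sim_config(prof, list(NR = c(count = 90, dwell_s = 60),
                                     C = c(count = 10, dwell_s = 113))),
               "lower EMG tone")
})

test_that("simulation is seed-deterministic, bit-identical", {
  cfg <- preset_config("OXMC_ablated", "dark", duration = 3600, seed = 9)
  t1 <- simulate_hypnogram(cfg)
  t2 <- simulate_hypnogram(cfg)
  expect_identical(as.character(t1$hypnogram), as.character(t2$hypnogram))
  r1 <- synthesize_signals(t1)
  r2 <- synthesize_signals(t2)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$emg, r2$emg)
  t3 <- simulate_hypnogram(preset_config("OXMC_ablated", "dark",
                                         duration = 3600, seed = 10))
  expect_false(identical(as.character(t1$hypnogram),
                         as.character(t3$hypnogram)))
})

test_that("structural invariants hold for every generated hypnogram", {
  for (seed in 1:10) {
    truth <- simulate_hypnogram(preset_config("OXMC_ablated", "dark",
                                              duration = 10800, seed = seed))
    expect_true(audit_structure(truth$hypnogram))
    x <- as.character(truth$hypnogram)
    r <- rle(x)
    expect_true(all(r$lengths[r$values == "C"] >= 3))
    after_d <- r$values[which(r$values == "D") + 1]
    expect_true(all(after_d == "W", na.rm = TRUE))
  }
})

test_that("realized DT dwell matches the configured mean (20 seeds)", {
  durs <- unlist(lapply(1:20, function(s) {
    truth <- simulate_hypnogram(preset_config("OXMC_ablated", "dark", seed = s))
    b <- extract_bouts(truth$hypnogram)
    b$duration_s[b$state == "D"]
  }))
  sem <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 14.4), 2 * sem)
})

test_that("empirical occupancy matches the semi-Markov stationary solution", {
  cfg <- preset_config("intact", "dark", duration = 40000) # 10,000 epochs
  # analytic oracle: stationary visit rates of the embedded chain, weighted
  # by the configured mean dwell per visit
  p_r <- cfg$transition_weights["NR", "R"]
  P <- rbind(W = c(0, 1, 0),
             NR = c(1 - p_r, 0, p_r),
             R = c(1, 0, 0))
  pi_v <- Re(eigen(t(P))$vectors[, 1])
  pi_v <- pi_v / sum(pi_v)
  d <- vapply(c("W", "NR", "R"), function(s) cfg$profiles[[s]]$dwell_mean, 0)
  occ_expected <- pi_v * d / sum(pi_v * d)

  occ <- t(vapply(1:50, function(s) {
    cfg_s <- preset_config("intact", "dark", duration = 40000, seed = s)
    x <- as.character(simulate_hypnogram(cfg_s)$hypnogram)
    vapply(c("W", "NR", "R"), function(st) mean(x == st), 0)
  }, numeric(3)))
  for (j in 1:3) {
    se <- stats::sd(occ[, j]) / sqrt(nrow(occ))
    expect_lt(abs(mean(occ[, j]) - occ_expected[j]), 3 * se)
  }
})

test_that("state-conditional signals carry the configured signatures", {
  # NREM-only: delta power dominates theta
  nr_truth <- manual_truth(rep("NR", 200), seed = 50)
  f_nr <- pipeline_features(synthesize_signals(nr_truth))
  expect_gt(mean(f_nr$delta), mean(f_nr$theta))
  # REM-only: theta fraction above 0.5 in over 95% of epochs
  r_truth <- manual_truth(rep("R", 200), seed = 51)
  f_r <- pipeline_features(synthesize_signals(r_truth))
  expect_gt(mean(f_r$theta_fraction > 0.5), 0.95)
  # label-conditional ordering on a mixed recording
  truth <- simulate_hypnogram(preset_config("OXMC_ablated", "dark",
                                            duration = 3600, seed = 52))
  f <- pipeline_features(synthesize_signals(truth))
  lab <- as.character(truth$hypnogram)
  if (sum(lab == "R") > 0) {
    expect_gt(mean(f$delta[lab == "NR"] > stats::median(f$delta[lab == "R"])),
              0.99)
    expect_gt(mean(f$theta[lab == "R"] > stats::median(f$theta[lab == "NR"])),
              0.99)
  }
  # atonia states lie below wake EMG
  expect_gt(stats::median(f$emg_integral[lab == "W"]),
            5 * stats::median(f$emg_integral[lab != "W"]))
})

test_that("zero-amplitude profiles give all-zero signals", {
  zero <- c(delta = 0, theta = 0, alpha = 0, beta = 0)
  prof <- list(W = state_profile("W", zero, emg_tone = 0),
               NR = state_profile("NR", zero, emg_tone = 0),
               R = state_profile("R", zero, emg_tone = 0))
  cfg <- sim_config(prof, list(NR = c(count = 120, dwell_s = 60),
                               R = c(count = 10, dwell_s = 60)),
                    duration = 600, seed = 1)
  rec <- synthesize_signals(simulate_hypnogram(cfg))
  expect_true(all(rec$eeg == 0))
  expect_true(all(rec$emg == 0))
})

test_that("raising a band amplitude raises that band's power, matched seeds", {
  base_truth <- manual_truth(rep("NR", 150), seed = 60)
  hi_truth <- base_truth
  hi_truth$config$profiles$NR$band_amplitudes["delta"] <- 80 # default 60
  f_lo <- pipeline_features(synthesize_signals(base_truth))
  f_hi <- pipeline_features(synthesize_signals(hi_truth))
  d_delta <- mean(f_hi$delta) - mean(f_lo$delta)
  expect_gt(d_delta, 0)
  # theta band nearly untouched (same noise stream; only window leakage moves)
  expect_lt(abs(mean(f_hi$theta) - mean(f_lo$theta)), 0.05 * d_delta)
})

test_that("simulation artifacts round-trip through EDF, TSV and YAML", {
  cfg <- preset_config("OXMC_ablated", "dark", duration = 1200, seed = 70)
  truth <- simulate_hypnogram(cfg)
  rec <- synthesize_signals(truth)
  paths <- file.path(tempdir(), c("sim.edf", "sim.tsv", "sim.yaml"))
  write_simulation(truth, rec, paths[1], paths[2], paths[3])
  expect_true(all(file.exists(paths)))
  back <- read_hypnogram(paths[2])
  expect_identical(as.character(back), as.character(truth$hypnogram))
  y <- yaml::read_yaml(paths[3])
  expect_equal(y$fs, 128)
  expect_equal(y$profiles$D$dwell_dist$mean_s, 14.4)
  expect_equal(y$transition_weights$D$W, 1)
  rec2 <- read_recording(paths[1], "edf")
  expect_equal(length(rec2$eeg), length(rec$eeg))
})
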