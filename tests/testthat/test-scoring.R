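test_that("reference estimation separates known EMG modes", {
  set.seed(30)
  n <- 300
  feats <- make_features(
    emg = c(rlnorm(n, log(2), 0.3), rlnorm(n, log(20), 0.3)),
    delta = c(rlnorm(n, log(100), 0.2), rlnorm(n, log(20), 0.2)),
    theta = rep(10, 2 * n))
  refs <- estimate_references(feats)
  expect_gt(refs$emg_wake_thresh, 4)
  expect_lt(refs$emg_wake_thresh, 16)
  expect_lt(refs$emg_atonia_thresh, refs$emg_wake_thresh)
  expect_gt(refs$nrem_delta_ref, 50) # median delta of the low-EMG epochs
})

test_that("an all-wake recording yields a labeled unimodal failure", {
  set.seed(31)
  feats <- make_features(emg = rlnorm(600, log(20), 0.25),
                         delta = rep(20, 600), theta = rep(20, 600))
  expect_error(estimate_references(feats), "unimodal")
  expect_error(estimate_references(feats[1:100, ]), "at least 500")
})

test_that("references are scale-equivariant and labels scale-invariant", {
  set.seed(32)
  n <- 400
  feats <- make_features(
    emg = c(rlnorm(n, log(2), 0.3), rlnorm(n, log(20), 0.3)),
    delta = c(rlnorm(n, log(100), 0.2), rlnorm(n, log(20), 0.2)),
    theta = c(rlnorm(n, log(30), 0.2), rlnorm(n, log(20), 0.2)))
  scaled <- feats
  scaled$emg_integral <- feats$emg_integral * 2
  for (b in c("delta", "theta", "alpha", "beta")) scaled[[b]] <- feats[[b]] * 4
  r1 <- estimate_references(feats)
  r2 <- estimate_references(scaled)
  expect_equal(r2$emg_wake_thresh, 2 * r1$emg_wake_thresh, tolerance = 1e-8)
  expect_equal(r2$emg_atonia_thresh, 2 * r1$emg_atonia_thresh, tolerance = 1e-8)
  expect_equal(r2$nrem_delta_ref, 4 * r1$nrem_delta_ref, tolerance = 1e-8)
  expect_identical(classify_base(feats, r1), classify_base(scaled, r2))
})

test_that("base rules: EMG precedence, theta rule, NREM default", {
  refs <- toy_refs()
  feats <- make_features(emg = c(20, 2, 2, 2),
                         delta = c(10, 10, 120, 120),
                         theta = c(200, 200, 70, 30))
  # theta fractions: .94, .94, .31, .2 on rows 1,2,3,4
  expect_identical(classify_base(feats, refs), c("W", "R", "NR", "NR"))
  # high EMG wins regardless of spectrum
  expect_identical(classify_base(make_features(30, 10, 300), refs), "W")
  # missing features are flagged unscorable
  f <- make_features(c(2, NA), c(100, 100), c(30, 30))
  expect_identical(classify_base(f, refs), c("NR", NA))
})

test_that("cataplexy rule: length and antecedent-wake requirements", {
  refs <- toy_refs()
  seq_ok <- make_features(emg = c(rep(20, 12), rep(1, 3), 20),
                          delta = rep(10, 16), theta = rep(100, 16))
  lab <- classify_base(seq_ok, refs)
  out <- detect_cataplexy(lab, seq_ok, refs)
  expect_identical(out[13:15], rep("C", 3))
  expect_identical(out[c(1:12, 16)], rep("W", 13))

  # only 8 wake epochs before the arrest: stays REM
  seq_short_w <- make_features(emg = c(rep(1, 2), rep(20, 8), rep(1, 3), 20),
                               delta = rep(10, 14), theta = rep(100, 14))
  lab2 <- classify_base(seq_short_w, refs)
  expect_false(any(detect_cataplexy(lab2, seq_short_w, refs) == "C"))

  # 2-epoch (8 s) atonia run: below the 10 s rule, stays REM
  seq_2ep <- make_features(emg = c(rep(20, 10), 1, 1, 20),
                           delta = rep(10, 13), theta = rep(100, 13))
  lab3 <- classify_base(seq_2ep, refs)
  out3 <- detect_cataplexy(lab3, seq_2ep, refs)
  expect_identical(out3[11:12], c("R", "R"))
})

test_that("DT rule: delta/theta criteria, termination by wake", {
  refs <- toy_refs()
  base <- function(tail_emg = 20, delta_d = 80) {
    make_features(emg = c(rep(20, 10), rep(1, 4), tail_emg),
                  delta = c(rep(10, 10), rep(delta_d, 4), 10),
                  theta = c(rep(10, 10), rep(80, 4), 10))
  }
  f <- base()
  lab <- detect_cataplexy(classify_base(f, refs), f, refs)
  out <- detect_dt_sleep(lab, f, refs)
  expect_identical(out[11:14], rep("D", 4)) # delta = 0.8 x NREM reference

  f_low <- base(delta_d = 30) # delta criterion (60%) fails
  lab_low <- detect_cataplexy(classify_base(f_low, refs), f_low, refs)
  expect_false(any(detect_dt_sleep(lab_low, f_low, refs) == "D"))

  f_nr <- base(tail_emg = 2) # followed by NREM, not wake
  lab_nr <- detect_cataplexy(classify_base(f_nr, refs), f_nr, refs)
  expect_false(any(detect_dt_sleep(lab_nr, f_nr, refs) == "D"))

  # run cut off by the recording end is flagged, not labeled
  f_end <- base()[1:14, ]
  lab_end <- detect_cataplexy(classify_base(f_end, refs), f_end, refs)
  out_end <- detect_dt_sleep(lab_end, f_end, refs)
  expect_false(any(out_end == "D"))
  expect_length(attr(out_end, "dt_flagged_end"), 1)

  bad_refs <- toy_refs()
  bad_refs$nrem_delta_ref <- NA_real_
  expect_error(detect_dt_sleep(lab, f, bad_refs), "nrem_delta_ref")
})

test_that("raising the DT delta ratio never increases DT epochs", {
  for (seed in 1:8) {
    feats <- random_toy_table(200, seed)
    lab <- classify_base(feats, toy_refs())
    lab <- detect_cataplexy(lab, feats, toy_refs())
    n06 <- sum(detect_dt_sleep(lab, feats, toy_refs(dt_delta_ratio = 0.6)) == "D")
    n08 <- sum(detect_dt_sleep(lab, feats, toy_refs(dt_delta_ratio = 0.8)) == "D")
    expect_lte(n08, n06)
  }
})

test_that("permuting epochs breaks contextual detection but not base counts", {
  refs <- toy_refs()
  f <- make_features(emg = c(rep(20, 12), rep(1, 3), 20),
                     delta = rep(10, 16), theta = rep(100, 16))
  lab <- detect_cataplexy(classify_base(f, refs), f, refs)
  expect_equal(sum(lab == "C"), 3)
  set.seed(33)
  perm <- c(seq(1, 15, by = 2), seq(2, 16, by = 2)) # interleave: no wake run
  fp <- f[perm, ]
  labp <- detect_cataplexy(classify_base(fp, refs), fp, refs)
  expect_equal(sum(labp == "W"), sum(lab == "W"))
  expect_equal(sum(labp == "C"), 0)
})

test_that("scoring a recording is deterministic and logs its thresholds", {
  truth <- simulate_hypnogram(preset_config("OXMC_ablated", "dark",
                                            duration = 2400, seed = 40))
  rec <- synthesize_signals(truth)
  h1 <- score_recording(rec)
  h2 <- score_recording(rec)
  expect_identical(as.character(h1), as.character(h2))
  log <- attr(h1, "log")
  expect_equal(unname(log$emg_band["high"]), 0.98 * 64)
  expect_true(is.finite(log$emg_wake_thresh))
  expect_s3_class(attr(h1, "references"), "scoring_references")
})

test_that("intact-preset recordings are scored without cataplexy or DT sleep", {
  truth <- simulate_hypnogram(preset_config("intact", "dark",
                                            duration = 7200, seed = 41))
  hyp <- score_recording(synthesize_signals(truth))
  expect_equal(sum(hyp %in% c("C", "D")), 0)
})

test_that("evaluate_scoring: identity, degenerate and random predictions", {
  truth <- c("W", "W", "NR", "R", "C", "C", "C", "D", "W")
  ev <- evaluate_scoring(truth, truth)
  expect_true(all(diag(ev$confusion) == rowSums(ev$confusion)))
  expect_true(all(ev$recall[c("W", "NR", "R", "C", "D")] == 1))
  expect_equal(ev$accuracy, 1)

  allw <- evaluate_scoring(rep("W", 9), truth)
  expect_equal(unname(allw$recall["W"]), 1)
  expect_true(all(allw$recall[c("NR", "R", "C", "D")] == 0))

  set.seed(42)
  n <- 5000
  t5 <- sample(VIGILANCE_STATES, n, replace = TRUE)
  p5 <- sample(VIGILANCE_STATES, n, replace = TRUE)
  evr <- evaluate_scoring(p5, t5)
  expect_true(all(abs(evr$recall - 0.2) < 0.04))

  expect_error(evaluate_scoring(rep("W", 3), truth), "length")
})
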