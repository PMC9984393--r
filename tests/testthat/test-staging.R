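test_that("pure tones are assigned entirely to their band", {
  rules <- staging_rules()
  emg <- rnorm(128 * 4, 0, 0.1)
  f_delta <- compute_epoch_features(tone_epoch(2), emg, 128, rules, 1)
  expect_equal(f_delta$frac_delta, 1)
  expect_equal(f_delta$frac_fast, 0)
  expect_equal(f_delta$frac_theta, 0)

  f_fast <- compute_epoch_features(tone_epoch(20), emg, 128, rules, 1)
  expect_equal(f_fast$frac_fast, 1)

  f_theta <- compute_epoch_features(tone_epoch(7), emg, 128, rules, 1)
  expect_equal(f_theta$frac_theta, 1)
})

test_that("a half-delta half-fast epoch splits its fractions 50/50", {
  fs <- 128
  eeg <- c(tone_epoch(2, fs = fs, epoch_s = 2), tone_epoch(20, fs = fs,
                                                           epoch_s = 2))
  f <- compute_epoch_features(eeg, rnorm(fs * 4, 0, 0.1), fs,
                              staging_rules(), 1)
  expect_equal(f$frac_delta, 0.5)
  expect_equal(f$frac_fast, 0.5)
})

test_that("band fractions match the brute-force spectral-argmax oracle", {
  rules <- staging_rules()
  fs <- 128
  set.seed(31)
  for (rep in 1:5) {
    # mixture of tones and noise, different band per quarter epoch
    eeg <- c(tone_epoch(runif(1, 1, 3), fs, 1),
             tone_epoch(runif(1, 6, 9), fs, 1),
             tone_epoch(runif(1, 14, 22), fs, 1),
             rnorm(fs, 0, 0.5))
    dom <- dominant_freq_oracle(eeg, fs, subwindow_s = 0.5, pad_s = 2)
    f <- compute_epoch_features(eeg, rnorm(fs * 4), fs, rules, 1)
    expect_equal(f$frac_fast, mean(dom > 12, na.rm = FALSE))
    expect_equal(f$frac_delta, mean(dom >= 0.5 & dom <= 4))
    expect_equal(f$frac_theta, mean(dom >= 5 & dom <= 10))
  }
})

test_that("all-zero EEG yields zero fractions, not an error", {
  f <- compute_epoch_features(rep(0, 512), rnorm(512), 128,
                              staging_rules(), 1)
  expect_equal(f$frac_fast + f$frac_delta + f$frac_theta, 0)
})

test_that("length mismatches are rejected", {
  expect_error(compute_epoch_features(rnorm(100), rnorm(512), 128,
                                      staging_rules(), 1), "samples")
})

test_that("band fractions are invariant to EEG amplitude scaling", {
  fs <- 128
  set.seed(8)
  eeg <- tone_epoch(3, fs) + rnorm(fs * 4, 0, 0.3)
  f1 <- compute_epoch_features(eeg, rnorm(fs * 4), fs, staging_rules(), 1)
  f2 <- compute_epoch_features(eeg * 1000, rnorm(fs * 4), fs,
                               staging_rules(), 1)
  expect_equal(f1[c("frac_fast", "frac_delta", "frac_theta")],
               f2[c("frac_fast", "frac_delta", "frac_theta")])
})

test_that("EMG calibration separates two well-separated clusters", {
  set.seed(12)
  rms <- c(rnorm(50, 1, 0.01), rnorm(50, 10, 0.01))
  thr <- calibrate_emg_threshold(rms)
  expect_gt(thr, max(rms[1:50]))
  expect_lt(thr, min(rms[51:100]))
})

test_that("degenerate EMG distributions yield an infinite threshold", {
  expect_equal(calibrate_emg_threshold(rep(2, 50)), Inf)
  # within 1% relative range still counts as degenerate
  expect_equal(calibrate_emg_threshold(seq(1, 1.005, length.out = 20)), Inf)
  expect_error(calibrate_emg_threshold(numeric(0)), "no EMG")
  expect_error(calibrate_emg_threshold(rep(1, 5)), "at least 10")
})

test_that("calibration agrees with the brute-force 1-D 2-means oracle", {
  set.seed(13)
  cases <- list(
    c(rep(1, 19), 10),                       # single outlier among constants
    c(rnorm(30, 0.2, 0.02), rnorm(30, 2, 0.2)),
    exp(rnorm(40, 0, 0.3)) * rep(c(1, 8), 20))
  for (x in cases) {
    thr <- calibrate_emg_threshold(x)
    centers <- brute_2means_oracle(log(x))
    expect_equal(log(thr), mean(centers), tolerance = 1e-8)
  }
})

test_that("the staging rules fire in the documented order", {
  rules <- staging_rules()
  feats <- function(fast = 0, delta = 0, theta = 0, high = FALSE) {
    structure(list(frac_fast = fast, frac_delta = delta, frac_theta = theta,
                   emg_rms = 1, emg_high = high), class = "epoch_features")
  }
  # fast waveforms >10% of the time with high EMG: wake
  expect_equal(stage_epoch(feats(fast = 0.5, high = TRUE), rules), "WAKE")
  # delta >30% of the time, fast <10%, low EMG: NREM
  expect_equal(stage_epoch(feats(delta = 0.9), rules), "NREM")
  # theta >20% of the time with low EMG: REM
  expect_equal(stage_epoch(feats(theta = 0.4, delta = 0.1, fast = 0.05),
                           rules), "REM")
  # nothing fires: fallback (wake by default, configurable)
  expect_equal(stage_epoch(feats(fast = 0.05, delta = 0.1, theta = 0.1),
                           rules), "WAKE")
  rules_nrem <- staging_rules(fallback = "NREM")
  expect_equal(stage_epoch(feats(), rules_nrem), "NREM")
  # high EMG blocks NREM and REM even with sleep-like spectra
  expect_equal(stage_epoch(feats(delta = 0.9, high = TRUE), rules), "WAKE")
})

test_that("every feature combination receives exactly one label", {
  rules <- staging_rules()
  grid <- expand.grid(fast = c(0, 0.05, 0.2), delta = c(0, 0.2, 0.5),
                      theta = c(0, 0.1, 0.3), high = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    f <- structure(list(frac_fast = grid$fast[i], frac_delta = grid$delta[i],
                        frac_theta = grid$theta[i], emg_rms = 1,
                        emg_high = grid$high[i]), class = "epoch_features")
    s <- stage_epoch(f, rules)
    expect_true(s %in% c("WAKE", "NREM", "REM"))
    expect_length(s, 1)
  }
})

test_that("recordings are staged deterministically with full recovery", {
  set.seed(55)
  truth <- simulate_hypnogram(hypnogram_params(duration_h = 0.5, seed = 61))
  sig <- synthesize_signals(truth, signal_params(noise_amp = 0.05,
                                                 seed = 62))
  s1 <- stage_recording(sig)
  s2 <- stage_recording(sig)
  expect_identical(as.character(s1), as.character(s2))
  expect_length(s1, length(truth))
  expect_gte(mean(as.character(s1) == as.character(truth)), 0.95)
})

test_that("staging is invariant to a common EMG scale factor", {
  truth <- simulate_hypnogram(hypnogram_params(duration_h = 0.25, seed = 63))
  sig <- synthesize_signals(truth, signal_params(seed = 64))
  scaled <- sig
  scaled$emg <- sig$emg * 37.5
  expect_identical(as.character(stage_recording(sig)),
                   as.character(stage_recording(scaled)))
})

test_that("uniform pure-delta recordings stage as all NREM", {
  n_ep <- 12
  fs <- 128
  eeg <- t(replicate(n_ep, tone_epoch(2, fs)))
  set.seed(3)
  # identical near-zero EMG in every epoch: calibration is degenerate, so
  # every epoch is classified low-EMG
  emg <- matrix(rep(rnorm(fs * 4, 0, 1e-3), each = n_ep), n_ep)
  staged <- stage_recording(list(eeg = eeg, emg = emg, fs = fs))
  expect_true(all(staged == "NREM"))
})

test_that("majority smoothing removes isolated single-epoch flips", {
  h <- hypnogram(c("NREM", "NREM", "WAKE", "NREM", "NREM"))
  expect_equal(as.character(smooth_hypnogram(h, 3)), rep("NREM", 5))
  expect_equal(as.character(smooth_hypnogram(h, 1)), as.character(h))
})
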