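test_that("feature extraction on trivial and WK2 waves", {
  flat <- pressure_wave(rep(100, 500), fs = 500, T = 1)
  f <- extract_features(flat)
  expect_equal(f$SBP, 100); expect_equal(f$DBP, 100)
  expect_equal(f$MBP, 100); expect_equal(f$cPP, 0)
  expect_equal(f$HR, 60)

  p <- wk_params(R = 1.2, C = 1, T = 1, ts = 0.3, SV = 81.7)
  w <- solve_wk2_periodic(p, half_sine_flow(1, 0.3, 81.7))
  f2 <- extract_features(w)
  expect_lt(abs(f2$MBP / (1.2 * 81.7 / 1) - 1), 1e-6)  # conservation oracle
  expect_equal(f2$cPP, f2$SBP - f2$DBP)
  expect_true(f2$DBP <= f2$MBP && f2$MBP <= f2$SBP)
})

test_that("feature extraction is sampling-rate invariant (250 Hz - 2 kHz)", {
  d <- rand_wk_draws(5, seed = 21)
  for (i in seq_len(nrow(d))) {
    lo <- solve_subject(d[i, ], fs = 250)
    hi <- solve_subject(d[i, ], fs = 2000)
    flo <- extract_features(lo$wave)
    fhi <- extract_features(hi$wave)
    for (col in c("SBP", "DBP", "MBP", "cPP"))
      expect_lt(abs(flo[[col]] - fhi[[col]]), 0.2)
  }
})

test_that("MBP estimation formulas reproduce their arithmetic", {
  expect_equal(estimate_mbp(131, 77, formula = "dbp_third_pp"), 94.82)
  expect_equal(estimate_mbp(120, 80, formula = "sbp_dbp_weighted"), 96.8)
  expect_equal(estimate_mbp(120, 80, formula = "dbp_third_pp_plus5"), 98.2)
  expect_equal(estimate_mbp(120, 80, HR = 60, formula = "hr_adjusted"),
               80 + (0.33 + 0.072) * 40)
  expect_equal(estimate_mbp(120, 80, formula = "geometric_mean"),
               sqrt(120 * 80))
  expect_error(estimate_mbp(120, 80, formula = "nope"), "unknown")
  expect_error(estimate_mbp(120, 80, formula = "waveform_mean"),
               "extract_features")
  expect_error(estimate_mbp(120, 80, formula = "hr_adjusted"), "HR")
  expect_error(estimate_mbp(80, 120, formula = "dbp_third_pp"), "SBP >= DBP")
})

test_that("scalar MBP formulas coincide when PP = 0 (offset formula aside)", {
  # the fixed "+5 mmHg" variant deliberately keeps its offset at PP = 0
  set.seed(4)
  for (v in runif(20, 60, 120)) {
    for (fid in setdiff(mbp_formulas(), c("waveform_mean", "dbp_third_pp_plus5")))
      expect_equal(estimate_mbp(v, v, HR = 70, formula = fid), v,
                   tolerance = 1e-12)
    expect_equal(estimate_mbp(v, v, formula = "dbp_third_pp_plus5"), v + 5)
  }
})

test_that("calibration hits its anchors and preserves shape", {
  s <- solve_subject(rand_wk_draws(1, seed = 5))
  cal <- calibrate_wave(s$wave, 77, 100)
  expect_lt(abs(min(cal$samples) - 77), 1e-9)
  expect_lt(abs(mean(cal$samples) - 100), 1e-9)
  f <- extract_features(cal)
  expect_equal(f$DBP, 77); expect_equal(f$MBP, 100)

  # identity when the wave already satisfies the anchors
  again <- calibrate_wave(cal, 77, 100)
  expect_equal(again$samples, cal$samples, tolerance = 1e-12)

  # closed-form gain: perturbing the anchors rescales cPP proportionally
  x <- s$wave$samples
  a <- (102 - 80) / (mean(x) - min(x))
  cal2 <- calibrate_wave(s$wave, 80, 102)
  expect_lt(abs((max(cal2$samples) - min(cal2$samples)) -
                a * (max(x) - min(x))), 1e-9)

  expect_error(calibrate_wave(pressure_wave(rep(90, 100), 100, 1), 77, 100),
               "flat")
  expect_error(calibrate_wave(s$wave, 100, 77), "MBP_ref > DBP_ref")
})

test_that("Savitzky-Golay smoothing reproduces cubic signals exactly", {
  t <- seq(0, 1, length.out = 500)
  x <- 2 + t - 3 * t^2 + 0.5 * t^3
  sm <- savitzky_golay(x, window = 21, order = 3)
  expect_lt(max(abs(sm - x)), 1e-8)
  expect_error(savitzky_golay(x, window = 20), "odd")
})

test_that("beat averaging recovers the clean cycle", {
  co <- generate_population(population_config(n = 2, seed = 6),
                            keep_waveforms = TRUE)
  clean <- co$pressure[[1]]

  # identical tiled cycles: exact recovery (up to circular phase)
  rec0 <- add_measurement_noise(clean, noise_config(0, 0, 0, 0, 0), seed = 1)
  avg0 <- average_beats(rec0, smoothing = FALSE)
  expect_lt(aligned_rmse(avg0$samples, clean$samples), 1e-9)

  # white noise, ~20 s of beats
  recw <- add_measurement_noise(clean,
                                noise_config(white_sd = 1, drift_amplitude = 0,
                                             cycle_jitter_sd = 0), seed = 2)
  expect_lt(aligned_rmse(average_beats(recw)$samples, clean$samples), 0.5)

  # slow drift only: detrending removes it
  recd <- add_measurement_noise(clean,
                                noise_config(white_sd = 0, drift_amplitude = 5,
                                             cycle_jitter_sd = 0), seed = 3)
  expect_lt(aligned_rmse(average_beats(recd, smoothing = FALSE)$samples,
                         clean$samples), 0.5)

  # full default noise model, end to end
  recf <- add_measurement_noise(clean, noise_config(), seed = 4)
  expect_lt(aligned_rmse(average_beats(recf)$samples, clean$samples), 0.5)

  short <- pressure_wave(rep(clean$samples, 2), clean$fs, clean$T, n_beats = 2)
  expect_error(average_beats(short), "cycle")
})
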