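test_that("decay fit recovers an exact exponential to machine precision", {
  fs <- 1000; T <- 1; ts <- 0.3
  t <- (seq_len(fs * T) - 1) / fs
  w <- pressure_wave(90 * exp(-t / 1.3), fs, T)
  expect_lt(abs(fit_diastolic_decay(w, ts) - 1.3), 1e-10)
})

test_that("decay fit matches ground truth on WK2 waves", {
  d <- rand_wk_draws(10, seed = 31)
  for (i in seq_len(nrow(d))) {
    s <- solve_subject(d[i, ])
    tau <- d$R[i] * d$C[i]
    expect_lt(abs(fit_diastolic_decay(s$wave, s$params$ts) / tau - 1), 1e-3)
    tnl <- fit_diastolic_decay(s$wave, s$params$ts,
                               decay_fit_config(method = "nonlinear_ls"))
    expect_lt(abs(tnl / tau - 1), 1e-3)
  }
})

test_that("decay fit is unbiased under white measurement noise", {
  s <- solve_subject(data.frame(R = 1.0, C = 1.3, T = 0.9, tsf = 1 / 3, SV = 75))
  set.seed(99)
  est <- replicate(1000, {
    noisy <- s$wave
    noisy$samples <- noisy$samples + rnorm(length(noisy$samples), 0, 1)
    fit_diastolic_decay(noisy, s$params$ts)
  })
  expect_lt(abs(mean(est) - 1.3) / 1.3, 0.02)
})

test_that("decay fit error handling", {
  fs <- 1000; t <- (seq_len(fs) - 1) / fs
  neg <- pressure_wave(90 * exp(-t / 1.3) - 60, fs, 1)
  expect_error(fit_diastolic_decay(neg, 0.3), "nonlinear_ls")
  grow <- pressure_wave(50 * exp(t / 2), fs, 1)
  expect_error(fit_diastolic_decay(grow, 0.3), "decay")
  tiny <- pressure_wave(exp(-(0:11) / 100), 12, 1)
  expect_error(fit_diastolic_decay(tiny, 0.3), "fewer than 10")
})

test_that("pulse pressure method recovers the generating compliance", {
  d <- rand_wk_draws(8, seed = 41)
  for (i in seq_len(nrow(d))) {
    s <- solve_subject(d[i, ])
    C_hat <- ppm_compliance(s$wave, s$flow, d$R[i])
    expect_lt(abs(C_hat / d$C[i] - 1), 1e-6)
  }
})

test_that("PPM objective is strictly decreasing in C and root monotone in PP", {
  s <- solve_subject(data.frame(R = 1.1, C = 1.2, T = 0.8, tsf = 0.35, SV = 70))
  pp_at <- function(C) {
    p <- wk_params(1.1, C, 0.8, 0.35 * 0.8, 70)
    w <- solve_wk2_periodic(p, s$flow)
    max(w$samples) - min(w$samples)
  }
  grid <- seq(0.1, 5, length.out = 30)
  expect_true(all(diff(vapply(grid, pp_at, numeric(1))) < 0))

  # doubling the measured PP strictly decreases the fitted compliance
  C1 <- ppm_compliance(s$wave, s$flow, 1.1)
  doubled <- s$wave
  doubled$samples <- (doubled$samples - min(doubled$samples)) * 2 +
    min(doubled$samples)
  C2 <- ppm_compliance(doubled, s$flow, 1.1)
  expect_lt(C2, C1)

  # unattainably large measured PP -> bracketing error with diagnostics
  huge <- s$wave
  huge$samples <- huge$samples * 100
  expect_error(ppm_compliance(huge, s$flow, 1.1), "outside")
})

test_that("harmonic-truncated PPM stays close to the full-waveform variant", {
  s <- solve_subject(data.frame(R = 1.0, C = 1.1, T = 0.75, tsf = 0.35, SV = 72))
  C_full <- ppm_compliance(s$wave, s$flow, 1.0)
  C_h5 <- ppm_compliance(s$wave, s$flow, 1.0, harmonics = 5)
  expect_lt(abs(C_h5 / C_full - 1), 0.1)
})

test_that("resistance and formula arithmetic", {
  expect_equal(peripheral_resistance(100, 100), 1)
  expect_equal(peripheral_resistance(100, 4.9 * 1000 / 60), 1.2245, tolerance = 1e-4)
  expect_equal(peripheral_resistance(0, 50), 0)
  expect_error(peripheral_resistance(100, 0), "positive")

  expect_equal(tau_formula(1, 100, 54, 0.7), 0.7 * 100 / 54)
  expect_equal(tau_formula(1, 54, 54, 1), 1)
  expect_error(tau_formula(1, 100, 0, 0.7), "positive")
  expect_error(tau_formula(1, 100, 54, 0), "positive")

  expect_equal(tau_reference(1.0, 1.1), 1.1)
  expect_equal(tau_reference(2, 0.5), 1.0)
  expect_error(tau_reference(-1, 1), "positive")
})

test_that("per-subject exact coefficient closes the algebraic identity", {
  co <- generate_population(population_config(n = 100, seed = 17))
  k_exact <- co$C * co$cPP / co$SV_ml
  # with the exact Windkessel mean pressure R*SV/T the pulse pressure
  # cancels and tau = R*C is recovered to machine precision
  mbp_exact <- co$R * co$SV_ml / co$T_s
  tau_hat <- tau_formula(co$T_s, mbp_exact, co$cPP, kprime = 1) * k_exact
  expect_lt(max(abs(tau_hat / co$tau_true - 1)), 1e-12)
  # the waveform-integral MBP agrees with the exact mean to quadrature error
  tau_hat_wave <- k_exact * co$T_s * co$MBP / co$cPP
  expect_lt(max(abs(tau_hat_wave / co$tau_true - 1)), 1e-6)
})

test_that("tau_estimates agree on clean WK2 data", {
  d <- rand_wk_draws(5, seed = 51)
  for (i in seq_len(nrow(d))) {
    s <- solve_subject(d[i, ])
    est <- tau_estimates(s$params, s$wave, s$flow)
    expect_lt(abs(est$tau_exp / est$tau_ref - 1), 1e-3)
    expect_lt(abs(est$R_est * est$C_ppm / est$tau_ref - 1), 1e-5)
  }
})
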