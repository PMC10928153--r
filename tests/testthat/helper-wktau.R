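# Shared fixtures, all built in code.

# Random plausible WK2 parameter draws (physiological ranges, fixed seed).
rand_wk_draws <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    R = runif(n, 0.6, 1.6),
    C = runif(n, 0.4, 2.2),
    T = runif(n, 0.5, 1.1),
    tsf = runif(n, 0.30, 0.40),
    SV = runif(n, 40, 110)
  )
}

solve_subject <- function(d, fs = 1000, shape = half_sine_flow) {
  pars <- wk_params(d$R, d$C, d$T, d$tsf * d$T, d$SV)
  fl <- shape(d$T, d$tsf * d$T, d$SV, fs)
  list(params = pars, flow = fl, wave = solve_wk2_periodic(pars, fl))
}

# RMSE between a recovered cycle and the clean one, minimised over circular
# phase shift (the averaged beat starts at the detected foot, not at
# ejection onset).
aligned_rmse <- function(recovered, clean_samples) {
  L <- length(recovered)
  cl <- stats::approx((0:length(clean_samples)) / length(clean_samples),
                      c(clean_samples, clean_samples[1]),
                      xout = (seq_len(L) - 1) / L)$y
  best <- Inf
  for (s in 0:(L - 1)) {
    rot <- c(cl[(s + 1):L], cl[seq_len(s)])
    best <- min(best, sqrt(mean((recovered - rot)^2)))
  }
  best
}

# Minimal cohort-like tibble for fitting tests that need no waveforms.
fake_cohort <- function(n, seed = 1) {
  set.seed(seed)
  T_s <- runif(n, 0.5, 1.1)
  MBP <- runif(n, 80, 120)
  cPP <- runif(n, 30, 70)
  k <- runif(n, 0.6, 0.75)
  tibble::tibble(
    id = seq_len(n),
    age = runif(n, 35, 55),
    gender = sample(c("M", "F"), n, replace = TRUE),
    T_s = T_s, MBP = MBP, cPP = cPP, HR = 60 / T_s,
    SBP = MBP + 0.6 * cPP, DBP = MBP + 0.6 * cPP - cPP,
    tau_true = k * T_s * MBP / cPP
  )
}
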