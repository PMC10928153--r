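#' Reference time constant
#'
#' The diastolic decay time constant of the two-element Windkessel is the
#' product of total peripheral resistance and total arterial compliance,
#' `tau = R * C`. With both parameters known (as in the synthetic cohort)
#' this is the ground-truth reference against which the other estimators are
#' judged. Note that the cohort mean of per-subject `tau` is not the product
#' of the cohort means of `R` and `C` (the parameters correlate through the
#' population structure), so summary rows must average per-subject values.
#'
#' @param R Peripheral resistance (mmHg s/mL), > 0. Vectorised.
#' @param C Arterial compliance (mL/mmHg), > 0. Vectorised.
#' @return `tau` (s).
#' @export
tau_reference <- function(R, C) {
  if (any(!is.finite(R)) || any(R <= 0) || any(!is.finite(C)) || any(C <= 0))
    stop("`R` and `C` must be positive")
  R * C
}

#' Total peripheral resistance from mean pressure and cardiac output
#'
#' `R = MBP / CO`, with cardiac output in mL/s (divide L/min by 60 and
#' multiply by 1000, i.e. 4.9 L/min = 81.67 mL/s).
#'
#' @param MBP Mean blood pressure (mmHg), >= 0. Vectorised.
#' @param CO Cardiac output (mL/s), > 0.
#' @return Resistance (mmHg s/mL).
#' @export
peripheral_resistance <- function(MBP, CO) {
  if (any(!is.finite(CO)) || any(CO <= 0)) stop("`CO` must be positive")
  if (any(!is.finite(MBP)) || any(MBP < 0)) stop("`MBP` must be >= 0")
  MBP / CO
}

#' Closed-form time constant from pressure features
#'
#' The central relation of the package: `tau = kprime * T * MBP / cPP`, with
#' the heart period `T` in seconds. In consistent seconds units the
#' dimensionless coefficient equals the per-subject ratio `C * cPP / SV`
#' (when heart rate in beats/min is used instead of `T`, the tabulated
#' coefficient is 60 times larger).
#'
#' @param T Heart period (s), > 0. Vectorised.
#' @param MBP Mean blood pressure (mmHg), > 0.
#' @param cPP Central pulse pressure (mmHg), > 0.
#' @param kprime Fitted dimensionless coefficient, > 0.
#' @return Estimated `tau` (s).
#' @examples
#' tau_formula(T = 1, MBP = 100, cPP = 54, kprime = 0.7)  # 1.296 s
#' @export
tau_formula <- function(T, MBP, cPP, kprime) {
  if (any(!is.finite(cPP)) || any(cPP <= 0)) stop("`cPP` must be positive")
  vals <- c(T, MBP, kprime)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("`T`, `MBP` and `kprime` must be positive")
  kprime * T * MBP / cPP
}

#' Diastolic decay fit configuration
#'
#' The fitting window starts `window_start * T` seconds after the end of
#' ejection (default 5% of the period, skipping dicrotic-notch artifacts)
#' and ends at `window_end * T`. The default method is a log-linear least
#' squares fit (deterministic); `nonlinear_ls` fits the exponential directly
#' by `nls` and tolerates non-positive samples.
#'
#' @param window_start,window_end Window bounds as fractions of the period,
#'   `0 <= window_start < window_end <= 1`.
#' @param method `"log_linear"` or `"nonlinear_ls"`.
#' @return A `decay_fit_config` list.
#' @export
decay_fit_config <- function(window_start = 0.05, window_end = 1,
                             method = c("log_linear", "nonlinear_ls")) {
  method <- match.arg(method)
  if (window_start < 0 || window_start >= window_end || window_end > 1)
    stop("need 0 <= window_start < window_end <= 1")
  structure(list(window_start = window_start, window_end = window_end,
                 method = method), class = "decay_fit_config")
}

#' Fit a mono-exponential decay to the diastolic pressure
#'
#' Estimates `tau` by fitting `P(t) = P0 * exp(-t / tau)` to the diastolic
#' part of a single-cycle wave (the classical waveform-based route to the
#' time constant). For WK2 waves the diastole is exactly exponential, so the
#' fit recovers `R * C` to numerical precision.
#'
#' @param wave Single-cycle [pressure_wave()] with `t = 0` at ejection onset.
#' @param ts Ejection duration (s): diastole is `t > ts`.
#' @param cfg A [decay_fit_config()].
#' @return Fitted `tau` (s), > 0.
#' @export
fit_diastolic_decay <- function(wave, ts, cfg = decay_fit_config()) {
  stopifnot(inherits(wave, "pressure_wave"), inherits(cfg, "decay_fit_config"))
  if (wave$n_beats != 1) stop("`wave` must be a single cycle")
  t <- wave_times(wave)
  T <- wave$T
  sel <- t >= ts + cfg$window_start * T & t <= cfg$window_end * T
  if (sum(sel) < 10)
    stop("diastolic window holds fewer than 10 samples; raise fs or widen window")
  tt <- t[sel]
  pp <- wave$samples[sel]
  if (cfg$method == "log_linear") {
    if (any(pp <= 0))
      stop("non-positive pressure in window: log-linear fit impossible, ",
           "use method = 'nonlinear_ls'")
    slope <- stats::cov(tt, log(pp)) / stats::var(tt)
    if (slope >= 0) stop("window does not decay: fitted tau would be <= 0")
    return(-1 / slope)
  }
  # nonlinear least squares, seeded from the log-linear slope where possible
  tau0 <- if (all(pp > 0)) {
    s <- stats::cov(tt, log(pp)) / stats::var(tt)
    if (s < 0) -1 / s else NA_real_
  } else NA_real_
  if (!is.finite(tau0))
    tau0 <- (max(tt) - min(tt)) /
      max(log(max(abs(pp)) / max(abs(pp[length(pp)]), 1e-6)), 0.1)
  fit <- stats::nls(pp ~ P0 * exp(-tt / tau),
                    start = list(P0 = max(pp), tau = abs(tau0)),
                    algorithm = "port", lower = c(P0 = 0, tau = 1e-6),
                    control = stats::nls.control(maxiter = 500, warnOnly = TRUE))
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) stop("decay fit failed: non-positive tau")
  tau
}

# Low-pass a flow wave to its first `k` harmonics of the heart period.
.truncate_harmonics <- function(flow, k) {
  q <- flow$samples
  n <- length(q)
  Q <- stats::fft(q)
  keep <- rep(FALSE, n)
  keep[1:(k + 1)] <- TRUE           # DC + first k positive harmonics
  keep[n - (1:k) + 1] <- TRUE       # conjugate bins
  Q[!keep] <- 0
  fl <- flow
  fl$samples <- Re(stats::fft(Q, inverse = TRUE)) / n
  fl$shape <- paste0(flow$shape, "_lp", k)
  fl
}

#' Pulse pressure method for total arterial compliance
#'
#' Iteratively refines the compliance of a two-element Windkessel (with the
#' measured flow and a given peripheral resistance) until the model's pulse
#' pressure matches the measured pulse pressure. The predicted pulse
#' pressure is strictly decreasing in `C`, so the root is bracketed and
#' found to `|delta PP| < tol`.
#'
#' @param pressure Measured single-cycle [pressure_wave()] (only its pulse
#'   pressure is used).
#' @param flow The subject's [half_sine_flow()]/[triangular_flow()] wave.
#' @param R Peripheral resistance (mmHg s/mL), > 0.
#' @param harmonics Optional integer: low-pass the flow to its first
#'   `harmonics` harmonics before solving (classical 1st-5th-harmonic
#'   variant); `NULL` (default) uses the full waveform.
#' @param tol Absolute pulse-pressure matching tolerance (mmHg).
#' @param C_range Bracketing interval for the compliance (mL/mmHg).
#' @return Estimated compliance `C` (mL/mmHg).
#' @export
ppm_compliance <- function(pressure, flow, R, harmonics = NULL, tol = 1e-8,
                           C_range = c(1e-3, 100)) {
  stopifnot(inherits(pressure, "pressure_wave"), inherits(flow, "flow_wave"))
  if (R <= 0) stop("`R` must be positive")
  if (abs(pressure$T - flow$T) > 1e-9)
    stop("`pressure` and `flow` must share the same heart period")
  pp_meas <- max(pressure$samples) - min(pressure$samples)
  if (pp_meas <= 0) stop("measured pulse pressure must be positive")
  use_fourier <- !is.null(harmonics)
  fl <- flow
  if (use_fourier) fl <- .truncate_harmonics(flow, as.integer(harmonics))
  pred_pp <- function(C) {
    pars <- wk_params(R, C, flow$T, flow$ts, flow$SV)
    w <- solve_wk2_periodic(pars, fl,
                            method = if (use_fourier) "fourier" else "analytic")
    max(w$samples) - min(w$samples)
  }
  f <- function(C) pred_pp(C) - pp_meas
  flo <- f(C_range[1])
  fhi <- f(C_range[2])
  if (flo < 0 || fhi > 0)
    stop("measured PP (", signif(pp_meas, 6), " mmHg) outside the range ",
         "attainable for C in [", C_range[1], ", ", C_range[2], "]: ",
         "predicted PP spans [", signif(pp_meas + fhi, 6), ", ",
         signif(pp_meas + flo, 6), "]")
  root <- stats::uniroot(f, interval = C_range, tol = 1e-13, maxiter = 2000)
  C_hat <- root$root
  if (abs(f(C_hat)) > tol)
    warning("PPM converged to |delta PP| = ", signif(abs(f(C_hat)), 3),
            " mmHg > tol")
  C_hat
}

#' All tau estimates for one subject
#'
#' Convenience wrapper returning the three time-constant estimates
#' (reference product, diastolic decay fit, closed-form formula) together
#' with the pulse-pressure-method compliance and the feature-based
#' resistance, as one tibble row.
#'
#' @param params [wk_params()] ground truth.
#' @param pressure,flow The subject's solved waves.
#' @param kprime Coefficient for the closed-form formula.
#' @param cfg Decay-fit configuration.
#' @return One-row tibble: `tau_ref, tau_exp, tau_formula, C_ppm, R_est`.
#' @export
tau_estimates <- function(params, pressure, flow, kprime = 0.7,
                          cfg = decay_fit_config()) {
  feats <- extract_features(pressure)
  co <- params$SV / params$T
  r_est <- peripheral_resistance(feats$MBP, co)
  tibble::tibble(
    tau_ref = tau_reference(params$R, params$C),
    tau_exp = fit_diastolic_decay(pressure, params$ts, cfg),
    tau_formula = tau_formula(feats$T_s, feats$MBP, feats$cPP, kprime),
    C_ppm = ppm_compliance(pressure, flow, r_est),
    R_est = r_est
  )
}
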