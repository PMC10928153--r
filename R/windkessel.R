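#' Two-element Windkessel subject parameters
#'
#' Bundle of the ground-truth hemodynamic parameters of one subject under the
#' two-element Windkessel (WK2) model: a total arterial compliance `C` in
#' parallel with a total peripheral resistance `R`, driven by an ejection
#' flow wave of duration `ts` within a heart period `T` delivering a stroke
#' volume `SV`. The diastolic decay time constant `tau = R * C` is a derived
#' quantity, never stored independently; it is reported by
#' [tau_reference()] and by the print method.
#'
#' @param R Total peripheral resistance (mmHg s/mL), > 0.
#' @param C Total arterial compliance (mL/mmHg), > 0.
#' @param T Heart period (s), > 0.
#' @param ts Ejection (systolic outflow) duration (s), in (0, T).
#' @param SV Stroke volume (mL), >= 0.
#'
#' @return An object of class `wk_params`.
#' @examples
#' p <- wk_params(R = 1, C = 1.1, T = 0.7, ts = 0.25, SV = 70)
#' tau_reference(p$R, p$C)
#' @export
wk_params <- function(R, C, T, ts, SV) {
  stopifnot(length(R) == 1, length(C) == 1, length(T) == 1,
            length(ts) == 1, length(SV) == 1)
  if (!is.finite(R) || R <= 0) stop("`R` must be a positive resistance (mmHg s/mL)")
  if (!is.finite(C) || C <= 0) stop("`C` must be a positive compliance (mL/mmHg)")
  if (!is.finite(T) || T <= 0) stop("`T` must be a positive heart period (s)")
  if (!is.finite(SV) || SV < 0) stop("`SV` must be a non-negative stroke volume (mL)")
  if (!is.finite(ts) || ts <= 0 || ts >= T)
    stop("invalid ejection duration: `ts` must satisfy 0 < ts < T")
  structure(list(R = R, C = C, T = T, ts = ts, SV = SV), class = "wk_params")
}

#' @export
print.wk_params <- function(x, ...) {
  cat("<wk_params>  R =", x$R, "mmHg s/mL,  C =", x$C, "mL/mmHg\n")
  cat("  T =", x$T, "s,  ts =", x$ts, "s,  SV =", x$SV, "mL\n")
  cat("  tau = R*C =", x$R * x$C, "s\n")
  invisible(x)
}

#' Uniformly sampled single-cycle (or multi-beat) pressure wave
#'
#' Light-weight container for a pressure signal sampled at `fs` Hz. The time
#' origin (`t = 0`) is the ejection onset, so for WK2 waves the pressure
#' minimum falls at/near the start of the cycle. A single-cycle wave holds
#' `round(fs * T)` samples covering `[0, T)`; the wrap-around sample equals
#' the first one by periodicity, so the arithmetic mean of the samples is the
#' periodic trapezoidal time-average.
#'
#' @param samples Pressure samples (mmHg).
#' @param fs Sampling rate (Hz).
#' @param T Heart period (s) of one cycle.
#' @param n_beats Number of beats covered (1 for a single cycle).
#' @return An object of class `pressure_wave` with fields `samples`, `fs`,
#'   `T`, `n_beats`.
#' @export
pressure_wave <- function(samples, fs, T, n_beats = 1) {
  if (length(samples) == 0 || anyNA(samples))
    stop("pressure samples must be non-empty and free of NA/NaN")
  structure(list(samples = as.numeric(samples), fs = fs, T = T,
                 n_beats = n_beats), class = "pressure_wave")
}

#' @export
print.pressure_wave <- function(x, ...) {
  cat("<pressure_wave> ", length(x$samples), "samples @", x$fs, "Hz,",
      x$n_beats, "beat(s), T =", x$T, "s\n")
  cat("  range [", min(x$samples), ",", max(x$samples), "] mmHg\n")
  invisible(x)
}

#' Sample times of a wave
#' @param wave A `pressure_wave` or `flow_wave`.
#' @return Numeric vector of sample times (s), starting at 0.
#' @export
wave_times <- function(wave) (seq_along(wave$samples) - 1) / wave$fs

.new_flow_wave <- function(shape, T, ts, SV, fs, samples) {
  structure(list(shape = shape, T = T, ts = ts, SV = SV, fs = fs,
                 samples = as.numeric(samples)), class = "flow_wave")
}

#' @export
print.flow_wave <- function(x, ...) {
  cat("<flow_wave> shape =", x$shape, ", T =", x$T, "s, ts =", x$ts,
      "s, SV =", x$SV, "mL @", x$fs, "Hz\n")
  invisible(x)
}

# Period-commensurate sampling grid: n = round(fs * T) samples at t = k T / n,
# so one period tiles the grid exactly and the sample mean is the periodic
# trapezoidal time-average. The effective rate n / T is stored as `fs`.
.period_grid <- function(T, fs) {
  n <- round(fs * T)
  list(n = n, t = (seq_len(n) - 1) * T / n, fs = n / T)
}

.check_flow_args <- function(T, ts, SV, fs) {
  if (!is.finite(ts) || ts <= 0 || ts >= T)
    stop("invalid ejection duration: `ts` must satisfy 0 < ts < T")
  if (SV < 0) stop("`SV` must be non-negative")
  if (fs * ts < 10)
    stop("sampling rate too low to resolve systole: need fs * ts >= 10 samples")
}

#' Half-sine ejection flow wave
#'
#' Parametric aortic outflow `Q(t) = (pi * SV / (2 * ts)) * sin(pi * t / ts)`
#' on `[0, ts]` and zero for the rest of the cycle. The closed-form integral
#' over one period equals `SV` exactly.
#'
#' @inheritParams wk_params
#' @param fs Sampling rate (Hz); must resolve systole with >= 10 samples.
#' @return A `flow_wave` (mL/s samples over one period).
#' @examples
#' fl <- half_sine_flow(T = 1, ts = 0.3, SV = 70, fs = 1000)
#' max(fl$samples)            # ~ pi * 70 / 0.6
#' sum(fl$samples) / fl$fs    # ~ 70 mL
#' @export
half_sine_flow <- function(T, ts, SV, fs = 1000) {
  .check_flow_args(T, ts, SV, fs)
  g <- .period_grid(T, fs)
  q <- ifelse(g$t <= ts, pi * SV / (2 * ts) * sin(pi * g$t / ts), 0)
  q[q < 0] <- 0  # guard rounding at the very end of systole
  .new_flow_wave("half_sine", T, ts, SV, g$fs, q)
}

#' Triangular ejection flow wave
#'
#' Symmetric triangular outflow peaking at `2 * SV / ts` at mid-ejection;
#' zero in diastole. Included to probe the sensitivity of the fitted
#' pulse-pressure coefficient to the ejection profile.
#'
#' @inheritParams half_sine_flow
#' @return A `flow_wave`.
#' @export
triangular_flow <- function(T, ts, SV, fs = 1000) {
  .check_flow_args(T, ts, SV, fs)
  g <- .period_grid(T, fs)
  t <- g$t
  qp <- 2 * SV / ts
  q <- numeric(length(t))
  up <- t <= ts / 2
  dn <- t > ts / 2 & t <= ts
  q[up] <- qp * t[up] / (ts / 2)
  q[dn] <- qp * (ts - t[dn]) / (ts / 2)
  .new_flow_wave("triangular", T, ts, SV, g$fs, q)
}

# Systolic propagators: exact solution of C dP/dt = Q - P/R on [0, ts] given
# P(0) = P0, evaluated at times `t` (subset of [0, ts]); return the samples
# and the exact end value P(ts). Both are affine in P0, which the periodic
# solver exploits.
.systole_half_sine <- function(P0, t, R, C, ts, SV) {
  tau <- R * C
  w <- pi / ts
  A <- pi * SV / (2 * ts)
  amp <- A * R / (1 + (w * tau)^2)
  pp <- function(u) amp * (sin(w * u) - w * tau * cos(w * u))
  hom <- P0 - pp(0)
  list(p = hom * exp(-t / tau) + pp(t),
       end = hom * exp(-ts / tau) + pp(ts))
}

# Propagate one linear-forcing segment Q(u) = a + b*u, u in [0, L]:
# particular solution P_p(u) = R*(a + b*u) - R*b*tau.
.lin_seg <- function(Pstart, u, L, a, b, R, tau) {
  pp <- function(v) R * (a + b * v) - R * b * tau
  hom <- Pstart - pp(0)
  list(p = hom * exp(-u / tau) + pp(u),
       end = hom * exp(-L / tau) + pp(L))
}

.systole_triangular <- function(P0, t, R, C, ts, SV) {
  tau <- R * C
  h <- ts / 2
  b <- (2 * SV / ts) / h
  i1 <- t <= h
  s1 <- .lin_seg(P0, t[i1], h, a = 0, b = b, R = R, tau = tau)
  s2 <- .lin_seg(s1$end, t[!i1] - h, h, a = 2 * SV / ts, b = -b, R = R, tau = tau)
  p <- numeric(length(t))
  p[i1] <- s1$p
  p[!i1] <- s2$p
  list(p = p, end = s2$end)
}

#' Exact periodic solution of the two-element Windkessel
#'
#' Solves `C dP/dt = Q(t) - P/R` with the periodic boundary condition
#' `P(0) = P(T)` for a parametric ejection flow. Two paths are available:
#'
#' * `"analytic"` (default): piecewise closed form (integrating factor with
#'   sinusoidal or linear forcing). Because the systolic solution is affine
#'   in the unknown initial pressure, the periodic condition is solved
#'   linearly and the result is exact to machine precision; in particular the
#'   diastolic segment equals `P(ts) * exp(-(t - ts)/tau)` exactly.
#' * `"fourier"`: frequency-domain solution `P_hat = Q_hat * R / (1 + i w tau)`
#'   on the sampled flow. Exact for band-limited flows (used by the
#'   harmonic-truncated pulse pressure method), spectrally accurate otherwise;
#'   retained as an independent cross-check of the analytic path.
#'
#' With `SV = 0` the unique periodic solution is identically zero.
#'
#' @param params A [wk_params()] object.
#' @param flow A `flow_wave` sharing `T` and `ts` with `params`.
#' @param fs Sampling rate of the returned pressure wave (defaults to the
#'   flow's).
#' @param method `"analytic"` or `"fourier"`.
#' @return A [pressure_wave()] over one period, `t = 0` at ejection onset.
#' @examples
#' p <- wk_params(R = 1, C = 1.1, T = 0.8, ts = 0.28, SV = 70)
#' w <- solve_wk2_periodic(p, half_sine_flow(0.8, 0.28, 70))
#' mean(w$samples)            # = R * SV / T
#' @export
solve_wk2_periodic <- function(params, flow, fs = flow$fs,
                               method = c("analytic", "fourier")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "wk_params"), inherits(flow, "flow_wave"))
  if (abs(params$T - flow$T) > 1e-9 || abs(params$ts - flow$ts) > 1e-9)
    stop("`params` and `flow` must share the same T and ts")
  if (abs(params$SV - flow$SV) > 1e-9 * max(1, params$SV))
    stop("`params` and `flow` must share the same SV")
  tau <- params$R * params$C

  if (method == "fourier") {
    q <- flow$samples
    n <- length(q)
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)  # FFT bin frequencies
    fk <- k * flow$fs / n
    H <- params$R / (1 + 1i * 2 * pi * fk * tau)
    p <- Re(stats::fft(stats::fft(q) * H, inverse = TRUE)) / n
    return(pressure_wave(p, flow$fs, params$T))
  }

  g <- .period_grid(params$T, fs)
  n <- g$n
  t <- g$t
  fs <- g$fs
  sys <- t <= params$ts
  prop <- switch(flow$shape,
    half_sine = .systole_half_sine,
    triangular = .systole_triangular,
    stop("no analytic path for flow shape '", flow$shape,
         "'; use method = \"fourier\"")
  )
  ts_ <- params$ts
  # P(ts) is affine in P0: evaluate at P0 = 0 and P0 = 1, then impose
  # P(0) = P(ts) * exp(-(T - ts)/tau).
  b0 <- prop(0, numeric(0), params$R, params$C, ts_, params$SV)$end
  a1 <- prop(1, numeric(0), params$R, params$C, ts_, params$SV)$end - b0
  E <- exp(-(params$T - ts_) / tau)
  denom <- 1 - E * a1
  if (!is.finite(denom) || abs(denom) < 1e-14)
    stop("periodic solution did not converge: degenerate periodicity map")
  P0 <- E * b0 / denom
  s <- prop(P0, t[sys], params$R, params$C, ts_, params$SV)
  p <- numeric(n)
  p[sys] <- s$p
  p[!sys] <- s$end * exp(-(t[!sys] - ts_) / tau)
  pressure_wave(p, fs, params$T)
}
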