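#' Extract scalar features from a single-cycle pressure wave
#'
#' Systolic pressure is the sample maximum, diastolic the minimum, mean
#' pressure the periodic trapezoidal time-average (identical to the sample
#' mean on a uniform single-period grid), central pulse pressure their
#' difference, and heart rate `60 / T`.
#'
#' @param wave A single-cycle [pressure_wave()].
#' @param id Optional subject identifier carried into the output.
#' @return One-row tibble: `id, SBP, DBP, MBP, cPP, T_s, HR`.
#' @examples
#' p <- wk_params(R = 1.2, C = 1, T = 1, ts = 0.3, SV = 81.7)
#' w <- solve_wk2_periodic(p, half_sine_flow(1, 0.3, 81.7))
#' extract_features(w)$MBP  # ~ R * SV / T = 98.04
#' @export
extract_features <- function(wave, id = NA_integer_) {
  stopifnot(inherits(wave, "pressure_wave"))
  if (wave$n_beats != 1)
    stop("`wave` must be a single cycle; use average_beats() first")
  x <- wave$samples
  if (length(x) == 0 || anyNA(x)) stop("pressure samples contain NA/NaN or are empty")
  sbp <- max(x)
  dbp <- min(x)
  tibble::tibble(id = id, SBP = sbp, DBP = dbp, MBP = mean(x),
                 cPP = sbp - dbp, T_s = wave$T, HR = 60 / wave$T)
}

#' Mean blood pressure estimation formulas
#'
#' Identifiers of the clinical MBP estimation formulas supported by
#' [estimate_mbp()], in the order usually tabulated:
#' `waveform_mean` (the integral mean of the waveform — the package
#' baseline, available only where the waveform is; see
#' [extract_features()]), `sbp_dbp_weighted` (0.42 SBP + 0.58 DBP),
#' `dbp_third_pp` (DBP + 0.33 PP), `dbp_third_pp_plus5` (DBP + 0.33 PP + 5),
#' `hr_adjusted` (DBP + (0.33 + 0.0012 HR) PP), and `geometric_mean`
#' (sqrt(SBP * DBP)).
#'
#' @return Character vector of formula ids.
#' @export
mbp_formulas <- function() {
  c("waveform_mean", "sbp_dbp_weighted", "dbp_third_pp",
    "dbp_third_pp_plus5", "hr_adjusted", "geometric_mean")
}

#' Estimate mean blood pressure from cuff-style scalars
#'
#' Applies one of the clinical MBP formulas (see [mbp_formulas()]) to
#' systolic/diastolic pressure and, where required, heart rate. All formulas
#' coincide when SBP = DBP. The `waveform_mean` id cannot be computed from
#' scalars and raises an error pointing at [extract_features()].
#'
#' @param SBP,DBP Systolic and diastolic pressure (mmHg), `SBP >= DBP > 0`.
#'   Vectorised.
#' @param HR Heart rate (beats/min); required by `hr_adjusted`.
#' @param formula One id from [mbp_formulas()].
#' @return Estimated MBP (mmHg).
#' @examples
#' estimate_mbp(131, 77, formula = "dbp_third_pp")  # 94.8
#' @export
estimate_mbp <- function(SBP, DBP, HR = NULL, formula = "sbp_dbp_weighted") {
  if (!formula %in% mbp_formulas())
    stop("unknown MBP formula '", formula, "'; see mbp_formulas()")
  if (formula == "waveform_mean")
    stop("'waveform_mean' needs the sampled waveform; use extract_features()")
  if (any(DBP <= 0) || any(SBP < DBP))
    stop("need SBP >= DBP > 0")
  pp <- SBP - DBP
  switch(formula,
    sbp_dbp_weighted = 0.42 * SBP + 0.58 * DBP,
    dbp_third_pp = DBP + 0.33 * pp,
    dbp_third_pp_plus5 = DBP + 0.33 * pp + 5,
    hr_adjusted = {
      if (is.null(HR) || any(!is.finite(HR)) || any(HR <= 0))
        stop("formula 'hr_adjusted' needs HR > 0")
      DBP + (0.33 + 0.0012 * HR) * pp
    },
    geometric_mean = sqrt(SBP * DBP)
  )
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing by convolution. Coefficients are the
#' centre row of the polynomial projection matrix; edges (half a window at
#' each end) are returned unsmoothed.
#'
#' @param x Numeric signal.
#' @param window Odd window length in samples (default 51, i.e. 51 ms at
#'   1 kHz).
#' @param order Polynomial order (default 3); must be < window.
#' @return Smoothed signal, same length as `x`.
#' @export
savitzky_golay <- function(x, window = 51, order = 3) {
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  if (order >= window) stop("`order` must be smaller than `window`")
  m <- (window - 1) / 2
  J <- outer(-m:m, 0:order, "^")
  h <- J %*% solve(crossprod(J), t(J))[, m + 1]
  sm <- stats::filter(x, rev(as.numeric(h)), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Foot (cycle-onset) detection: estimate the period from the FFT-based
# autocorrelation, locate each upstroke as the local maximum of dp/dt, then
# take the preceding pressure minimum as the foot.
.detect_feet <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  # autocorrelation via zero-padded FFT; ac[k + 1] = sum_i xc[i] xc[i + k]
  X <- stats::fft(c(xc, numeric(n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(n)] / (2 * n)
  lo <- max(2L, round(0.25 * fs))
  hi <- min(n - 1L, round(2.5 * fs))
  if (hi <= lo + 2) stop("recording too short for cycle detection")
  seg <- ac[(lo + 1):(hi + 1)]
  L <- lo + which.max(seg) - 1L  # period in samples
  d <- diff(x)
  u1 <- which.max(d[seq_len(min(L + round(0.2 * L), n - 1))])
  ups <- integer(0)
  u <- u1
  while (u <= n - 1) {
    w0 <- max(1L, u - round(0.2 * L))
    w1 <- min(n - 1L, u + round(0.2 * L))
    u <- w0 + which.max(d[w0:w1]) - 1L
    ups <- c(ups, u)
    u <- u + L
  }
  feet <- vapply(ups, function(up) {
    w0 <- max(1L, as.integer(up - round(0.3 * L)))
    as.integer(w0 + which.min(x[w0:up]) - 1L)
  }, integer(1))
  feet <- unique(feet)
  if (length(feet) < 4)
    stop("insufficient data: need at least 3 complete cycles")
  list(feet = feet, period = L)
}

#' Average a multi-beat recording into one representative cycle
#'
#' Implements the standard tonometry processing chain: optional
#' Savitzky-Golay smoothing, identification of individual cycles at the
#' upstroke foot, per-cycle linear detrending so that the start and end
#' values of each cycle match, resampling of all cycles to a common length,
#' and pointwise averaging.
#'
#' @param recording A multi-beat [pressure_wave()] with >= 3 detectable
#'   cycles.
#' @param smoothing Apply [savitzky_golay()] before cycle detection and
#'   averaging (default `TRUE`).
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @return A single-cycle `pressure_wave` (the averaged beat).
#' @export
average_beats <- function(recording, smoothing = TRUE, sg_window = 51,
                          sg_order = 3) {
  stopifnot(inherits(recording, "pressure_wave"))
  x <- recording$samples
  fs <- recording$fs
  if (smoothing) x <- savitzky_golay(x, sg_window, sg_order)
  det <- .detect_feet(x, fs)
  feet <- det$feet
  ncyc <- length(feet) - 1
  lens <- diff(feet)
  Lout <- as.integer(round(stats::median(lens)))
  acc <- matrix(0, nrow = ncyc, ncol = Lout)
  for (k in seq_len(ncyc)) {
    cyc <- x[feet[k]:(feet[k + 1] - 1)]
    m <- length(cyc)
    # linear detrend: make the (wrapped) end value equal the start value
    endval <- x[feet[k + 1]]
    cyc <- cyc - (endval - cyc[1]) * (seq_len(m) - 1) / m
    # periodic grid: sample i sits at phase (i-1)/m, wrap value = start value
    acc[k, ] <- stats::approx((0:m) / m, c(cyc, cyc[1]),
                              xout = (seq_len(Lout) - 1) / Lout)$y
  }
  pressure_wave(colMeans(acc), fs, Lout / fs)
}

#' Calibrate a pressure wave to diastolic and mean anchors
#'
#' Affine recalibration `p' = a p + b` such that `min(p') = DBP_ref` and
#' `mean(p') = MBP_ref`, preserving the normalized waveform shape. This is
#' the usual carotid-tonometry calibration against cuff diastolic and
#' (brachial-derived) mean pressure; the closed-form gain is
#' `a = (MBP_ref - DBP_ref) / (mean(p) - min(p))`.
#'
#' @param wave A [pressure_wave()].
#' @param DBP_ref,MBP_ref Calibration anchors (mmHg), `MBP_ref > DBP_ref`.
#' @return The calibrated `pressure_wave`.
#' @export
calibrate_wave <- function(wave, DBP_ref, MBP_ref) {
  stopifnot(inherits(wave, "pressure_wave"))
  if (MBP_ref <= DBP_ref) stop("need MBP_ref > DBP_ref")
  x <- wave$samples
  rng <- mean(x) - min(x)
  if (rng <= 0) stop("flat wave cannot be calibrated (mean equals min)")
  a <- (MBP_ref - DBP_ref) / rng
  b <- DBP_ref - a * min(x)
  pressure_wave(a * x + b, wave$fs, wave$T, wave$n_beats)
}
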