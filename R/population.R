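#' Distribution specification for one population parameter
#'
#' @param family `"normal_truncated"` or `"uniform"`.
#' @param location Mean (normal) — ignored for uniform.
#' @param scale SD (normal) — ignored for uniform.
#' @param lower,upper Support bounds. For `"uniform"` these are the only
#'   parameters used.
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(family = c("normal_truncated", "uniform"),
                      location = NA_real_, scale = NA_real_,
                      lower, upper) {
  family <- match.arg(family)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("invalid distribution spec: need finite lower < upper")
  if (family == "normal_truncated" &&
      (!is.finite(location) || !is.finite(scale) || scale <= 0))
    stop("invalid distribution spec: truncated normal needs location and scale > 0")
  structure(list(family = family, location = location, scale = scale,
                 lower = lower, upper = upper), class = "dist_spec")
}

# Inverse-CDF draw (deterministic under the RNG stream, fully vectorised).
.draw_dist <- function(n, spec) {
  u <- stats::runif(n)
  if (spec$family == "uniform") return(spec$lower + u * (spec$upper - spec$lower))
  plo <- stats::pnorm(spec$lower, spec$location, spec$scale)
  phi <- stats::pnorm(spec$upper, spec$location, spec$scale)
  stats::qnorm(plo + u * (phi - plo), spec$location, spec$scale)
}

#' Measurement-noise configuration
#'
#' Imperfections of a ~20 s tonometry recording plus cuff calibration:
#' additive white noise, a slow baseline drift across the recording,
#' beat-to-beat cycle-length jitter, and errors on the diastolic/mean
#' calibration anchors. All defaults are modest values typical of carotid
#' applanation tonometry with oscillometric cuff calibration.
#'
#' @param white_sd White-noise SD (mmHg).
#' @param drift_amplitude Peak-to-peak slow drift over a recording (mmHg).
#' @param cycle_jitter_sd SD of per-beat period jitter (fraction of T).
#' @param calibration_dbp_sd SD of the diastolic calibration anchor (mmHg).
#' @param calibration_mbp_sd SD of the mean-pressure calibration anchor (mmHg).
#' @return A `noise_config` list.
#' @export
noise_config <- function(white_sd = 1, drift_amplitude = 2,
                         cycle_jitter_sd = 0.02,
                         calibration_dbp_sd = 3, calibration_mbp_sd = 3) {
  vals <- c(white_sd, drift_amplitude, cycle_jitter_sd,
            calibration_dbp_sd, calibration_mbp_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all noise parameters must be finite and >= 0")
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 cycle_jitter_sd = cycle_jitter_sd,
                 calibration_dbp_sd = calibration_dbp_sd,
                 calibration_mbp_sd = calibration_mbp_sd),
            class = "noise_config")
}

#' Virtual-population configuration
#'
#' Defaults reproduce the moments of the in silico cohort the package
#' emulates: truncated normals R ~ 1 +/- 0.2 mmHg s/mL, C ~ 1.1 +/- 0.5
#' mL/mmHg, T ~ 0.7 +/- 0.1 s, SV ~ 70 +/- 14 mL (from cardiac output
#' 6 +/- 1.2 L/min at T = 0.7 s), and ejection fraction of the period
#' ts/T ~ uniform(0.30, 0.40). Ages are uniform on 35-55 years with a 50/50
#' gender split; demographic effects on hemodynamics are off by default
#' (`age_c_slope = 0`). Brachial pulse pressure is modelled as central PP
#' times a per-subject amplification factor (default mean 57/45).
#'
#' @param n Number of subjects (>= 2).
#' @param seed Integer RNG seed; regeneration with the same seed is
#'   bit-identical.
#' @param distributions Named list of [dist_spec()] for `R`, `C`, `T`,
#'   `ts_fraction`, `SV`; defaults as above.
#' @param noise A [noise_config()], or `NULL` for noiseless waveforms.
#' @param brachial_amplification Length-2 numeric `c(mean, sd)` of the
#'   multiplicative central-to-brachial PP amplification.
#' @param age_range Length-2 numeric (years).
#' @param female_fraction Probability a subject is female.
#' @param age_c_slope Compliance change per year of age (mL/mmHg/year);
#'   negative values emulate arterial stiffening with age. Default 0.
#' @return A `population_config` list.
#' @export
population_config <- function(n, seed = 1L,
                              distributions = default_distributions(),
                              noise = NULL,
                              brachial_amplification = c(mean = 57 / 45, sd = 0.05),
                              age_range = c(35, 55),
                              female_fraction = 0.5,
                              age_c_slope = 0) {
  if (n < 2) stop("population needs n >= 2 subjects")
  need <- c("R", "C", "T", "ts_fraction", "SV")
  if (!all(need %in% names(distributions)))
    stop("`distributions` must name specs for: ", paste(need, collapse = ", "))
  for (nm in need) {
    sp <- distributions[[nm]]
    if (!inherits(sp, "dist_spec")) stop("distribution for ", nm, " is not a dist_spec")
    if (nm == "ts_fraction") {
      if (sp$lower <= 0 || sp$upper >= 1)
        stop("ts_fraction support must lie inside (0, 1)")
    } else if (sp$lower <= 0) {
      stop("support of ", nm, " must be positive")
    }
  }
  if (!is.null(noise) && !inherits(noise, "noise_config"))
    stop("`noise` must be NULL or a noise_config")
  if (brachial_amplification[[1]] <= 0 || brachial_amplification[[2]] < 0)
    stop("brachial amplification mean must be > 0 and sd >= 0")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 distributions = distributions, noise = noise,
                 brachial_amplification = brachial_amplification,
                 age_range = age_range, female_fraction = female_fraction,
                 age_c_slope = age_c_slope),
            class = "population_config")
}

#' @rdname population_config
#' @export
default_distributions <- function() {
  list(
    R = dist_spec("normal_truncated", 1.0, 0.2, 0.4, 1.8),
    C = dist_spec("normal_truncated", 1.1, 0.5, 0.2, 2.8),
    T = dist_spec("normal_truncated", 0.7, 0.1, 0.4, 1.1),
    ts_fraction = dist_spec("uniform", lower = 0.30, upper = 0.40),
    SV = dist_spec("normal_truncated", 70, 14, 25, 130)
  )
}

# Run code with a private RNG state seeded at `seed`; restores the caller's.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a seeded virtual cohort
#'
#' Draws `n` independent WK2 subjects from the configured parameter
#' distributions, solves each subject's periodic pressure wave, extracts its
#' scalar features and returns everything as one tibble (`CohortTable`), one
#' row per subject. Ground truth `tau_true = R * C` is exact by construction.
#'
#' @param config A [population_config()].
#' @param fs Sampling rate for the solved waveforms (Hz).
#' @param flow_shape `"half_sine"` (default) or `"triangular"`.
#' @param keep_waveforms If `TRUE`, retain `pressure` and `flow` list-columns
#'   (memory-heavy for large n).
#' @return A tibble with columns `id, age, gender, R, C, tau_true, T_s, ts_s,
#'   SV_ml, SBP, DBP, MBP, cPP, bPP, HR` (plus `pressure`, `flow`
#'   list-columns when requested). Features are extracted from the noiseless
#'   wave; measurement noise (if configured) is applied downstream by
#'   [add_measurement_noise()].
#' @examples
#' coh <- generate_population(population_config(n = 20, seed = 7))
#' all.equal(coh$tau_true, coh$R * coh$C)
#' @export
generate_population <- function(config, fs = 1000,
                                flow_shape = c("half_sine", "triangular"),
                                keep_waveforms = FALSE) {
  stopifnot(inherits(config, "population_config"))
  flow_shape <- match.arg(flow_shape)
  flow_fun <- switch(flow_shape, half_sine = half_sine_flow,
                     triangular = triangular_flow)
  n <- config$n
  d <- config$distributions
  draws <- .with_seed(config$seed, {
    R <- .draw_dist(n, d$R)
    C <- .draw_dist(n, d$C)
    T <- .draw_dist(n, d$T)
    tsf <- .draw_dist(n, d$ts_fraction)
    SV <- .draw_dist(n, d$SV)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    gender <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    amp <- stats::rnorm(n, config$brachial_amplification[[1]],
                        config$brachial_amplification[[2]])
    list(R = R, C = C, T = T, tsf = tsf, SV = SV, age = age,
         gender = gender, amp = pmax(amp, 0.5))
  })
  if (config$age_c_slope != 0) {
    mid <- mean(config$age_range)
    draws$C <- pmax(draws$C + config$age_c_slope * (draws$age - mid),
                    d$C$lower)
  }

  waves <- vector("list", n)
  flows <- if (keep_waveforms) vector("list", n) else NULL
  SBP <- DBP <- MBP <- numeric(n)
  for (i in seq_len(n)) {
    pars <- wk_params(draws$R[i], draws$C[i], draws$T[i],
                      draws$tsf[i] * draws$T[i], draws$SV[i])
    fl <- flow_fun(pars$T, pars$ts, pars$SV, fs)
    pw <- solve_wk2_periodic(pars, fl)
    SBP[i] <- max(pw$samples)
    DBP[i] <- min(pw$samples)
    MBP[i] <- mean(pw$samples)
    if (keep_waveforms) {
      waves[[i]] <- pw
      flows[[i]] <- fl
    }
  }
  cPP <- SBP - DBP
  out <- tibble::tibble(
    id = seq_len(n),
    age = draws$age,
    gender = draws$gender,
    R = draws$R, C = draws$C,
    tau_true = draws$R * draws$C,
    T_s = draws$T,
    ts_s = draws$tsf * draws$T,
    SV_ml = draws$SV,
    SBP = SBP, DBP = DBP, MBP = MBP, cPP = cPP,
    bPP = brachial_surrogate(cPP, draws$amp),
    HR = 60 / draws$T
  )
  if (keep_waveforms) {
    out$pressure <- waves
    out$flow <- flows
  }
  out
}

#' Tile a clean cycle into a noisy multi-beat recording
#'
#' Emulates a ~20 s tonometry recording: the single clean cycle is repeated
#' with per-beat period jitter (each beat resampled in phase), then white
#' noise and a slow linear baseline drift are added. Deterministic under
#' `seed`.
#'
#' @param wave Single-cycle [pressure_wave()].
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @param duration Target recording length (s).
#' @return A multi-beat `pressure_wave`.
#' @export
add_measurement_noise <- function(wave, noise = noise_config(), seed = 1L,
                                  duration = 20) {
  stopifnot(inherits(wave, "pressure_wave"), inherits(noise, "noise_config"))
  if (wave$n_beats != 1) stop("`wave` must be a single cycle")
  fs <- wave$fs
  n_cyc <- ceiling(duration / wave$T)
  base <- wave$samples
  nb <- length(base)
  # closed cycle for phase interpolation (wrap sample = first sample)
  closed <- c(base, base[1])
  .with_seed(seed, {
    jit <- 1 + stats::rnorm(n_cyc, 0, noise$cycle_jitter_sd)
    jit <- pmax(jit, 0.5)
    beats <- lapply(jit, function(f) {
      m <- max(2L, round(nb * f))
      stats::approx(x = seq(0, 1, length.out = nb + 1), y = closed,
                    xout = (seq_len(m) - 1) / m)$y
    })
    x <- unlist(beats, use.names = FALSE)
    N <- length(x)
    drift <- noise$drift_amplitude * (seq_len(N) - 1) / max(N - 1, 1) -
      noise$drift_amplitude / 2
    x <- x + drift + stats::rnorm(N, 0, noise$white_sd)
    pressure_wave(x, fs, wave$T, n_beats = n_cyc)
  })
}

#' Brachial pulse pressure surrogate
#'
#' Models peripheral (brachial) pulse pressure as the central pulse pressure
#' scaled by a pulse-pressure amplification factor, `bPP = amplification *
#' cPP`. Vectorised.
#'
#' @param cPP Central pulse pressure (mmHg), > 0.
#' @param amplification Multiplicative amplification factor, > 0 (scalar or
#'   per-subject vector).
#' @return Brachial pulse pressure (mmHg).
#' @examples
#' brachial_surrogate(45, 57 / 45)  # 57
#' @export
brachial_surrogate <- function(cPP, amplification) {
  if (any(!is.finite(cPP)) || any(cPP <= 0))
    stop("`cPP` must be positive")
  if (any(!is.finite(amplification)) || any(amplification <= 0))
    stop("`amplification` must be positive")
  amplification * cPP
}
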