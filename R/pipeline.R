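#' Experiment configuration
#'
#' End-to-end two-stage design: derive the coefficient on a clean synthetic
#' cohort, then evaluate the fixed-coefficient formula on a held-out cohort
#' generated with a distinct seed (optionally through the noisy
#' recording/averaging/calibration chain). Defaults mirror the study design
#' the package emulates: derivation n = 3818 (noiseless), evaluation
#' n = 2263 with measurement noise, fixed coefficient 0.7.
#'
#' @param population A [population_config()] for the derivation cohort.
#' @param n_evaluate,seed_evaluate Size and seed of the held-out evaluation
#'   cohort (seed must differ from the derivation seed).
#' @param eval_noise A [noise_config()] applied to the evaluation cohort's
#'   waveforms, or `NULL` to evaluate on clean features.
#' @param kprime Fixed coefficient used at the evaluation stage.
#' @param fs Sampling rate (Hz).
#' @param flow_shape Ejection profile for both cohorts.
#' @param mbp_formula_ids Formulas for the sensitivity table.
#' @param output_dir Where [run_experiment()] writes its tables.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(population = population_config(n = 3818, seed = 1L),
                              n_evaluate = 2263, seed_evaluate = 2L,
                              eval_noise = noise_config(),
                              kprime = 0.7, fs = 1000,
                              flow_shape = "half_sine",
                              mbp_formula_ids = mbp_formulas(),
                              output_dir = tempfile("wktau_run")) {
  stopifnot(inherits(population, "population_config"))
  problems <- character(0)
  if (identical(as.integer(seed_evaluate), population$seed))
    problems <- c(problems, "derivation and evaluation cohorts must use distinct seeds")
  if (n_evaluate < 3) problems <- c(problems, "n_evaluate must be >= 3")
  if (kprime <= 0) problems <- c(problems, "kprime must be positive")
  if (!is.null(eval_noise) && !inherits(eval_noise, "noise_config"))
    problems <- c(problems, "eval_noise must be NULL or a noise_config")
  if (length(problems))
    stop("invalid experiment config:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(population = population,
                 n_evaluate = as.integer(n_evaluate),
                 seed_evaluate = as.integer(seed_evaluate),
                 eval_noise = eval_noise, kprime = kprime, fs = fs,
                 flow_shape = flow_shape,
                 mbp_formula_ids = mbp_formula_ids,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [experiment_config()] field-for-field; the `population`
#' block mirrors [population_config()] (with each distribution as a list of
#' `family, location, scale, lower, upper`). Missing fields take their
#' defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop_args <- y$population %||% list()
  # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
  names(pop_args)[names(pop_args) == "FALSE"] <- "n"
  if (!is.null(pop_args$distributions)) {
    pop_args$distributions <- lapply(pop_args$distributions,
                                     function(d) do.call(dist_spec, d))
  }
  if (!is.null(pop_args$noise))
    pop_args$noise <- do.call(noise_config, pop_args$noise)
  if (!is.null(pop_args$brachial_amplification))
    pop_args$brachial_amplification <- unlist(pop_args$brachial_amplification)
  population <- do.call(population_config, pop_args)
  args <- y[setdiff(names(y), "population")]
  if (!is.null(args$eval_noise)) args$eval_noise <- do.call(noise_config, args$eval_noise)
  do.call(experiment_config, c(list(population = population), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- CSV layer -------------------------------------------------------------

.schemas <- list(
  cohort = c("id", "age", "gender", "R", "C", "tau_true", "T_s", "ts_s", "SV_ml"),
  waveform = c("time_s", "pressure_mmHg"),
  features = c("id", "SBP", "DBP", "MBP", "cPP", "T_s", "HR"),
  tau = c("id", "tau_ref", "tau_exp", "tau_formula", "C_ppm", "R_est")
)

.check_schema <- function(df, kind, path) {
  missing <- setdiff(.schemas[[kind]], names(df))
  if (length(missing))
    stop("malformed ", kind, " CSV '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Cohort, feature, tau and waveform CSV round trips
#'
#' Plain-CSV persistence of the package's tables: the cohort schema is
#' `id,age,gender,R,C,tau_true,T_s,ts_s,SV_ml` plus any feature columns; a
#' waveform holds `time_s,pressure_mmHg` and optionally `flow_ml_s`. Values
#' round-trip losslessly (full double precision); readers validate the
#' header and name any missing columns.
#'
#' @param x Table to write (or, for waveforms, a [pressure_wave()]).
#' @param path File path.
#' @param flow Optional [half_sine_flow()]-style wave written alongside the
#'   pressure samples.
#' @return Readers return the table (tibble) or a `pressure_wave`; writers
#'   return `path` invisibly.
#' @name wktau_csv
NULL

#' @rdname wktau_csv
#' @export
write_cohort_csv <- function(x, path) {
  cols <- intersect(c(.schemas$cohort, "SBP", "DBP", "MBP", "cPP", "bPP", "HR"),
                    names(x))
  readr::write_csv(x[cols], path)
  invisible(path)
}

#' @rdname wktau_csv
#' @export
read_cohort_csv <- function(path) {
  .check_schema(readr::read_csv(path, show_col_types = FALSE), "cohort", path)
}

#' @rdname wktau_csv
#' @export
write_waveform_csv <- function(x, path, flow = NULL) {
  stopifnot(inherits(x, "pressure_wave"))
  df <- tibble::tibble(time_s = wave_times(x), pressure_mmHg = x$samples)
  if (!is.null(flow)) df$flow_ml_s <- flow$samples
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname wktau_csv
#' @export
read_waveform_csv <- function(path) {
  df <- .check_schema(readr::read_csv(path, show_col_types = FALSE),
                      "waveform", path)
  dt <- diff(df$time_s)
  fs <- 1 / stats::median(dt)
  pressure_wave(df$pressure_mmHg, fs, T = nrow(df) / fs)
}

#' @rdname wktau_csv
#' @export
write_feature_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname wktau_csv
#' @export
read_feature_csv <- function(path) {
  .check_schema(readr::read_csv(path, show_col_types = FALSE), "features", path)
}

#' @rdname wktau_csv
#' @export
write_tau_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname wktau_csv
#' @export
read_tau_csv <- function(path) {
  .check_schema(readr::read_csv(path, show_col_types = FALSE), "tau", path)
}

# ---- evaluation chain ------------------------------------------------------

#' Evaluate the fixed-coefficient formula on a cohort
#'
#' Applies `tau = kprime * T * MBP / cPP` per subject and compares against
#' the ground truth `tau_true`. When `noise` is supplied the features are
#' re-extracted through the measurement chain: the clean cycle is tiled into
#' a noisy multi-beat recording, beat-averaged, calibrated to perturbed
#' diastolic/mean anchors, and only then reduced to features — emulating
#' tonometry practice.
#'
#' @param cohort Cohort tibble (from [generate_population()]); must carry
#'   waveform list-columns when `noise` is used.
#' @param kprime Fixed coefficient.
#' @param noise Optional [noise_config()].
#' @param seed Base seed for the per-subject noise streams.
#' @return The cohort with added columns `tau_est` (formula) and, with
#'   noise, `MBP_meas`, `cPP_meas`, the measured features used.
#' @export
evaluate_formula <- function(cohort, kprime = 0.7, noise = NULL, seed = 1L) {
  if (is.null(noise)) {
    cohort$tau_est <- tau_formula(cohort$T_s, cohort$MBP, cohort$cPP, kprime)
    return(cohort)
  }
  if (is.null(cohort$pressure))
    stop("noisy evaluation needs waveforms: generate with keep_waveforms = TRUE")
  n <- nrow(cohort)
  mbp_m <- cpp_m <- t_m <- numeric(n)
  for (i in seq_len(n)) {
    rec <- add_measurement_noise(cohort$pressure[[i]], noise,
                                 seed = seed + i)
    avg <- average_beats(rec)
    anchors <- .with_seed(seed + i + 10^6, {
      c(dbp = cohort$DBP[i] + stats::rnorm(1, 0, noise$calibration_dbp_sd),
        mbp = cohort$MBP[i] + stats::rnorm(1, 0, noise$calibration_mbp_sd))
    })
    cal <- calibrate_wave(avg, anchors[["dbp"]],
                          max(anchors[["mbp"]], anchors[["dbp"]] + 1))
    f <- extract_features(cal)
    mbp_m[i] <- f$MBP
    cpp_m[i] <- f$cPP
    t_m[i] <- f$T_s
  }
  cohort$MBP_meas <- mbp_m
  cohort$cPP_meas <- cpp_m
  cohort$T_meas <- t_m
  cohort$tau_est <- tau_formula(t_m, mbp_m, cpp_m, kprime)
  cohort
}

#' Run the full derive-then-evaluate experiment
#'
#' Orchestrates the package's pipeline: (1) generate the derivation cohort
#' and fit the coefficient (pooled plus age/gender rows), (2) refit within
#' HR and MBP thirds, (3) rerun the fit under every MBP estimation formula,
#' (4) generate a held-out evaluation cohort with a distinct seed, apply the
#' fixed-coefficient formula (through the noise chain if configured) and
#' tabulate the agreement battery by age and gender, and (5) write all
#' tables, a scatter/Bland-Altman figure and a JSON manifest of seeds and
#' versions to `output_dir`. Reruns with the same config are bit-identical
#' in every CSV numeric cell.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the derivation cohort, fit tables
#'   (`fit_pooled`, `fit_table3`, `fit_table4`, `fit_table5`), the evaluated
#'   cohort and `evaluation_table6`, plus `paths` of everything written.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("deriving: generating cohort n = ", config$population$n,
      " (seed ", config$population$seed, ")")
  derive <- generate_population(config$population, fs = config$fs,
                                flow_shape = config$flow_shape)
  x <- .cohort_predictor(derive)
  pooled <- fit_kprime(derive$tau_true, x)

  t3 <- dplyr::bind_rows(
    tibble::tibble(variable = "all", group = "all", n = pooled$n,
                   kprime = pooled$kprime, R2 = pooled$R2),
    subgroup_fits(derive, "age"),
    subgroup_fits(derive, "gender")
  )
  t4 <- dplyr::bind_rows(subgroup_fits(derive, "HR"),
                         subgroup_fits(derive, "MBP"))
  t5 <- mbp_sensitivity(derive, config$mbp_formula_ids)

  say("evaluating: held-out cohort n = ", config$n_evaluate,
      " (seed ", config$seed_evaluate, ") with fixed kprime = ", config$kprime)
  eval_cfg <- config$population
  eval_cfg$n <- config$n_evaluate
  eval_cfg$seed <- config$seed_evaluate
  holdout <- generate_population(eval_cfg, fs = config$fs,
                                 flow_shape = config$flow_shape,
                                 keep_waveforms = !is.null(config$eval_noise))
  holdout <- evaluate_formula(holdout, kprime = config$kprime,
                              noise = config$eval_noise,
                              seed = config$seed_evaluate)
  t6 <- evaluate_by_group(holdout, "tau_est", "tau_true")

  paths <- list(
    cohort = file.path(config$output_dir, "derivation_cohort.csv"),
    fit_table3 = file.path(config$output_dir, "fit_table3.csv"),
    fit_table4 = file.path(config$output_dir, "fit_table4.csv"),
    fit_table5 = file.path(config$output_dir, "fit_table5.csv"),
    evaluation = file.path(config$output_dir, "evaluation_table6.csv"),
    figure = file.path(config$output_dir, "agreement_fig1.pdf"),
    manifest = file.path(config$output_dir, "manifest.json")
  )
  write_cohort_csv(derive, paths$cohort)
  readr::write_csv(t3, paths$fit_table3)
  readr::write_csv(t4, paths$fit_table4)
  readr::write_csv(t5, paths$fit_table5)
  readr::write_csv(t6, paths$evaluation)
  grDevices::pdf(paths$figure, width = 8, height = 4)
  print(plot_agreement(holdout$tau_est, holdout$tau_true))
  grDevices::dev.off()
  manifest <- list(
    package = "wktau",
    version = as.character(utils::packageVersion("wktau")),
    seeds = list(derivation = config$population$seed,
                 evaluation = config$seed_evaluate),
    n = list(derivation = config$population$n,
             evaluation = config$n_evaluate),
    kprime_fixed = config$kprime,
    kprime_fitted = pooled$kprime,
    flow_shape = config$flow_shape,
    fs = config$fs
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  say("wrote ", length(paths), " artifacts to ", config$output_dir)

  invisible(list(derivation = derive, fit_pooled = pooled, fit_table3 = t3,
                 fit_table4 = t4, fit_table5 = t5, evaluation_cohort = holdout,
                 evaluation_table6 = t6, paths = paths))
}
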