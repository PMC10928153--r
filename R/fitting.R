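#' Origin-constrained least-squares fit of the time constant coefficient
#'
#' Fits `tau = kprime * x` through the origin, where `x = T * MBP / cPP`
#' (seconds). The slope is `sum(x * tau) / sum(x^2)`, i.e. the
#' `x^2`-weighted mean of the per-subject ratios `tau / x`. The reported
#' R-squared uses the centered total sum of squares by default so it is
#' comparable with the with-intercept convention; the uncentered variant is
#' available for through-origin purists. With `intercept = TRUE` an ordinary
#' least-squares line is fitted instead and its slope returned as `kprime`.
#'
#' @param tau Reference time constants (s).
#' @param x Predictor `T * MBP / cPP` values (s); same length as `tau`.
#' @param intercept Fit an ordinary least-squares line instead of forcing
#'   the origin (default `FALSE`).
#' @param centered_r2 Use the centered total sum of squares for R-squared
#'   (default `TRUE`).
#' @param predictor_label Text label carried into the result.
#' @return An object of class `origin_fit`: list with `kprime`, `intercept`
#'   (0 for the origin fit), `R2`, `n`, `predictor_label`.
#' @examples
#' x <- c(1, 2, 3); fit_kprime(0.5 * x, x)$kprime  # 0.5
#' @export
fit_kprime <- function(tau, x, intercept = FALSE, centered_r2 = TRUE,
                       predictor_label = "T*MBP/cPP") {
  if (length(tau) != length(x)) stop("`tau` and `x` must have equal length")
  n <- length(tau)
  if (n < 2) stop("need at least 2 observations")
  if (!intercept && sum(x^2) == 0)
    stop("degenerate predictor: x is all zero")
  if (intercept) {
    sx <- x - mean(x)
    if (sum(sx^2) == 0) stop("degenerate predictor: x is constant")
    k <- sum(sx * (tau - mean(tau))) / sum(sx^2)
    b <- mean(tau) - k * mean(x)
  } else {
    k <- sum(x * tau) / sum(x^2)
    b <- 0
  }
  res <- tau - (k * x + b)
  tss <- if (centered_r2) sum((tau - mean(tau))^2) else sum(tau^2)
  structure(list(kprime = k, intercept = b, R2 = 1 - sum(res^2) / tss,
                 n = n, predictor_label = predictor_label),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat("<origin_fit> tau = ", format(x$kprime, digits = 4), " * ",
      x$predictor_label,
      if (x$intercept != 0) paste0(" + ", format(x$intercept, digits = 4)),
      "   (R2 = ", format(x$R2, digits = 3), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

# Equal-thirds split sizes; remainder subjects go to the outer groups
# (3818 -> 1273/1272/1273).
.tertile_sizes <- function(n) {
  base <- n %/% 3
  rem <- n %% 3
  c(base + (rem >= 1), base, base + (rem >= 2))
}

.cohort_predictor <- function(cohort, pp_col = "cPP") {
  cohort$T_s * cohort$MBP / cohort[[pp_col]]
}

#' Coefficient fits within cohort subgroups
#'
#' Refits the origin-constrained coefficient within subgroups of the cohort:
#' for `HR` or `MBP`, the cohort is sorted by the variable and split into
#' three equal-size groups (low / mid / high thirds, sizes
#' 1273/1272/1273 at n = 3818); for `age`, the bins are < 40, 40-50 and
#' > 50 years; for `gender`, M vs F.
#'
#' @param cohort Cohort tibble from [generate_population()] (needs
#'   `tau_true`, `T_s`, `MBP`, `cPP` and the grouping variable).
#' @param variable One of `"HR"`, `"MBP"`, `"age"`, `"gender"`.
#' @param ... Passed to [fit_kprime()].
#' @return Tibble with columns `variable, group, n, kprime, R2`.
#' @export
subgroup_fits <- function(cohort, variable = c("HR", "MBP", "age", "gender"),
                          ...) {
  variable <- match.arg(variable)
  x <- .cohort_predictor(cohort)
  tau <- cohort$tau_true
  if (variable %in% c("HR", "MBP")) {
    ord <- order(cohort[[variable]])
    sizes <- .tertile_sizes(nrow(cohort))
    grp_idx <- split(ord, rep(1:3, sizes))
    labels <- paste0(c("<Q1_", "[Q1,Q3]_", ">Q3_"), variable)
  } else if (variable == "age") {
    g <- cut(cohort$age, c(-Inf, 40, 50, Inf),
             labels = c("<40", "40-50", ">50"), right = TRUE)
    grp_idx <- split(seq_len(nrow(cohort)), g)
    labels <- names(grp_idx)
  } else {
    grp_idx <- split(seq_len(nrow(cohort)), cohort$gender)
    labels <- names(grp_idx)
  }
  rows <- lapply(seq_along(grp_idx), function(i) {
    idx <- grp_idx[[i]]
    if (length(idx) < 2)
      stop("subgroup '", labels[i], "' has fewer than 2 subjects")
    f <- fit_kprime(tau[idx], x[idx], ...)
    tibble::tibble(variable = variable, group = labels[i],
                   n = length(idx), kprime = f$kprime, R2 = f$R2)
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity of the coefficient to the MBP estimation formula
#'
#' Recomputes each subject's mean pressure with every requested formula,
#' refits the origin-constrained coefficient, and tabulates the results.
#' The `waveform_mean` id uses the cohort's integral-mean `MBP` column (the
#' package baseline).
#'
#' @param cohort Cohort tibble with `SBP`, `DBP`, `HR`, `MBP`, `cPP`, `T_s`,
#'   `tau_true`.
#' @param formula_ids Character vector of ids from [mbp_formulas()]
#'   (default: all six).
#' @param ... Passed to [fit_kprime()].
#' @return Tibble `formula, mean_MBP, sd_MBP, kprime, R2`, one row per
#'   formula.
#' @export
mbp_sensitivity <- function(cohort, formula_ids = mbp_formulas(), ...) {
  bad <- setdiff(formula_ids, mbp_formulas())
  if (length(bad)) stop("unknown MBP formula id(s): ", paste(bad, collapse = ", "))
  rows <- lapply(formula_ids, function(fid) {
    mbp <- if (fid == "waveform_mean") cohort$MBP
           else estimate_mbp(cohort$SBP, cohort$DBP, cohort$HR, fid)
    x <- cohort$T_s * mbp / cohort$cPP
    f <- fit_kprime(cohort$tau_true, x, ...)
    tibble::tibble(formula = fid, mean_MBP = mean(mbp), sd_MBP = stats::sd(mbp),
                   kprime = f$kprime, R2 = f$R2)
  })
  dplyr::bind_rows(rows)
}
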