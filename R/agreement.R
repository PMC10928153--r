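#' Method-agreement battery between estimated and reference values
#'
#' Computes the full evaluation battery used for method comparison:
#' Pearson's correlation, the intraclass correlation coefficient, ordinary
#' least-squares regression of the estimate on the reference with a
#' two-sided Wald t-test of the slope against zero, the root-mean-square
#' error normalized by the reference range (nRMSE, in percent), and the
#' Bland-Altman bias with 1.96-SD limits of agreement.
#'
#' The ICC defaults to the two-way random-effects, absolute-agreement,
#' single-measures form (ICC(2,1) / ICC(A,1)) — the appropriate variant when
#' the question is agreement, not mere consistency; the consistency form
#' ICC(3,1) is selectable.
#'
#' @param est Estimated values.
#' @param ref Reference values, same length, `n >= 3`, not constant.
#' @param icc_type `"ICC2_1"` (absolute agreement, default) or `"ICC3_1"`
#'   (consistency).
#' @return One-row tibble: `n, r, icc, slope, intercept, p_slope, nrmse_pct,
#'   bias, loa_low, loa_high`.
#' @examples
#' set.seed(1)
#' ref <- runif(50, 0.5, 2); est <- ref + rnorm(50, 0.1, 0.1)
#' evaluate_agreement(est, ref)
#' @export
evaluate_agreement <- function(est, ref, icc_type = c("ICC2_1", "ICC3_1")) {
  icc_type <- match.arg(icc_type)
  if (length(est) != length(ref)) stop("`est` and `ref` must have equal length")
  n <- length(est)
  if (n < 3) stop("insufficient data: need n >= 3 pairs")
  if (anyNA(est) || anyNA(ref)) stop("NA values in input")
  if (max(ref) == min(ref))
    stop("constant reference: r and nRMSE are undefined")

  d <- est - ref
  bias <- mean(d)
  sdd <- stats::sd(d)
  mr <- mean(ref)
  me <- mean(est)
  sxx <- sum((ref - mr)^2)
  sxy <- sum((ref - mr) * (est - me))
  syy <- sum((est - me)^2)
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)

  slope <- sxy / sxx
  intercept <- me - slope * mr
  res <- est - (intercept + slope * ref)
  se_slope <- sqrt(sum(res^2) / (n - 2) / sxx)
  p_slope <- if (se_slope == 0) 0 else
    2 * stats::pt(-abs(slope / se_slope), df = n - 2)

  nrmse <- 100 * sqrt(mean(d^2)) / (max(ref) - min(ref))

  icc <- .icc_two_way(est, ref, icc_type)

  tibble::tibble(n = n, r = r, icc = icc, slope = slope,
                 intercept = intercept, p_slope = p_slope,
                 nrmse_pct = nrmse, bias = bias,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd)
}

# Two-way mean squares for n subjects x 2 raters (est/ref), from explicit
# sums of squares; ICC(2,1) absolute agreement or ICC(3,1) consistency.
.icc_two_way <- function(est, ref, type) {
  n <- length(est)
  k <- 2
  y <- cbind(est, ref)
  grand <- mean(y)
  rowm <- rowMeans(y)
  colm <- colMeans(y)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC3_1") {
    denom <- msr + (k - 1) * mse
    if (denom == 0) return(1)
    (msr - mse) / denom
  } else {
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    if (denom == 0) return(1)
    (msr - mse) / denom
  }
}

#' Agreement battery per demographic group
#'
#' Applies [evaluate_agreement()] within each level of the requested
#' grouping columns (plus a pooled row), mirroring the usual age-bin and
#' gender breakdown of method-comparison tables. Age is binned < 40, 40-50,
#' > 50 years when `"age"` is among `group_cols`. Groups with fewer than 3
#' subjects are skipped with a warning.
#'
#' @param cohort Tibble holding the estimate and reference columns.
#' @param est_col,ref_col Column names (strings).
#' @param group_cols Character vector among `"age"`, `"gender"`; may be
#'   empty for the pooled row only.
#' @param icc_type Passed to [evaluate_agreement()].
#' @return Tibble: one row per group plus a `"all"` row, columns `group, n,
#'   r, icc, slope, intercept, p_slope, nrmse_pct, bias, loa_low, loa_high`.
#' @export
evaluate_by_group <- function(cohort, est_col, ref_col,
                              group_cols = c("age", "gender"),
                              icc_type = "ICC2_1") {
  est <- cohort[[est_col]]
  ref <- cohort[[ref_col]]
  if (is.null(est) || is.null(ref))
    stop("columns '", est_col, "' / '", ref_col, "' not found in cohort")
  groups <- list(all = seq_len(nrow(cohort)))
  if ("age" %in% group_cols) {
    ab <- cut(cohort$age, c(-Inf, 40, 50, Inf),
              labels = c("age<40", "age40-50", "age>50"), right = TRUE)
    groups <- c(groups, split(seq_len(nrow(cohort)), ab))
  }
  if ("gender" %in% group_cols)
    groups <- c(groups, split(seq_len(nrow(cohort)), cohort$gender))
  rows <- list()
  for (nm in names(groups)) {
    idx <- groups[[nm]]
    if (length(idx) < 3) {
      warning("group '", nm, "' has fewer than 3 subjects; skipped")
      next
    }
    rep_ <- evaluate_agreement(est[idx], ref[idx], icc_type = icc_type)
    rows[[nm]] <- dplyr::bind_cols(tibble::tibble(group = nm), rep_)
  }
  dplyr::bind_rows(rows)
}

#' Scatter and Bland-Altman panels for estimated vs reference values
#'
#' @param est,ref Paired values (s).
#' @param label Axis label stem (default "tau (s)").
#' @return A ggplot object with the two panels (faceted).
#' @export
plot_agreement <- function(est, ref, label = "tau (s)") {
  d <- est - ref
  bias <- mean(d)
  sdd <- stats::sd(d)
  df <- rbind(
    data.frame(panel = "scatter", x = ref, y = est),
    data.frame(panel = "bland_altman", x = (est + ref) / 2, y = d)
  )
  hl <- data.frame(panel = "bland_altman",
                   y = c(bias, bias - 1.96 * sdd, bias + 1.96 * sdd),
                   lt = c("bias", "loa", "loa"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(
      data = data.frame(panel = "scatter"),
      ggplot2::aes(slope = 1, intercept = 0), linetype = 2) +
    ggplot2::geom_hline(data = hl,
                        ggplot2::aes(yintercept = .data$y, linetype = .data$lt),
                        show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = paste("reference / mean", label),
                  y = paste("estimate / difference", label)) +
    ggplot2::theme_minimal()
}
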