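test_that("perfect agreement yields the identity report", {
  x <- c(0.8, 1.1, 1.4, 1.7, 2.0)
  rep_ <- evaluate_agreement(x, x)
  expect_equal(rep_$r, 1)
  expect_equal(rep_$icc, 1)
  expect_equal(rep_$bias, 0)
  expect_equal(c(rep_$loa_low, rep_$loa_high), c(0, 0))
  expect_equal(rep_$nrmse_pct, 0)
  expect_equal(rep_$slope, 1)
  expect_equal(rep_$intercept, 0)
})

test_that("a constant shift moves only bias (and absolute-agreement ICC)", {
  x <- c(0.8, 1.1, 1.4, 1.7, 2.0)
  rep_ <- evaluate_agreement(x + 0.1, x)
  expect_equal(rep_$bias, 0.1)
  expect_equal(c(rep_$loa_low, rep_$loa_high), c(0.1, 0.1))
  expect_equal(rep_$r, 1)
  expect_lt(rep_$icc, 1)   # ICC(2,1) penalises the shift
  expect_equal(evaluate_agreement(x + 0.1, x, icc_type = "ICC3_1")$icc, 1)
})

test_that("every statistic matches a brute-force oracle to 1e-10", {
  set.seed(50)
  ref <- runif(50, 0.5, 2.5)
  est <- 0.9 * ref + 0.2 + rnorm(50, 0, 0.15)
  rep_ <- evaluate_agreement(est, ref)

  expect_lt(abs(rep_$r - cor(est, ref)), 1e-10)

  fit <- lm(est ~ ref)
  sm <- summary(fit)$coefficients
  expect_lt(abs(rep_$slope - sm["ref", "Estimate"]), 1e-10)
  expect_lt(abs(rep_$intercept - sm["(Intercept)", "Estimate"]), 1e-10)
  expect_lt(abs(rep_$p_slope - sm["ref", "Pr(>|t|)"]), 1e-10)

  d <- est - ref
  expect_lt(abs(rep_$bias - mean(d)), 1e-10)
  expect_lt(abs(rep_$loa_low - (mean(d) - 1.96 * sd(d))), 1e-10)
  expect_lt(abs(rep_$loa_high - (mean(d) + 1.96 * sd(d))), 1e-10)
  expect_lt(abs(rep_$nrmse_pct -
                100 * sqrt(mean(d^2)) / (max(ref) - min(ref))), 1e-10)

  # ICC(2,1) via an independent two-way ANOVA decomposition
  long <- data.frame(y = c(est, ref),
                     subj = factor(rep(seq_along(est), 2)),
                     rater = factor(rep(c("est", "ref"), each = 50)))
  ms <- anova(lm(y ~ subj + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 50)
  expect_lt(abs(rep_$icc - icc_oracle), 1e-10)
})

test_that("limits of agreement have exactly the 2*1.96*SD width", {
  set.seed(51)
  ref <- runif(30, 1, 2)
  est <- ref + rnorm(30, 0, 0.2)
  rep_ <- evaluate_agreement(est, ref)
  expect_lt(abs((rep_$loa_high - rep_$loa_low) - 2 * 1.96 * sd(est - ref)),
            1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(evaluate_agreement(1:2, 1:2), "n >= 3")
  expect_error(evaluate_agreement(1:5, rep(1, 5)), "constant reference")
  expect_error(evaluate_agreement(1:4, 1:5), "equal length")
})

test_that("group-wise evaluation mirrors the pooled machinery", {
  set.seed(52)
  n <- 60
  co <- tibble::tibble(
    age = rep(c(37, 45, 53), each = n / 3),
    gender = rep(c("M", "F"), n / 2),
    tau_true = runif(n, 0.8, 2),
  )
  co$tau_est <- co$tau_true * 1.05 + rnorm(n, 0, 0.05)
  tab <- evaluate_by_group(co, "tau_est", "tau_true")
  expect_setequal(tab$group,
                  c("all", "age<40", "age40-50", "age>50", "M", "F"))

  # pooled bias is a weighted mean of the age-bin biases
  ages <- tab[tab$group %in% c("age<40", "age40-50", "age>50"), ]
  pooled <- tab$bias[tab$group == "all"]
  expect_lt(abs(pooled - sum(ages$bias * ages$n) / sum(ages$n)), 1e-12)
  expect_gte(pooled, min(ages$bias)); expect_lte(pooled, max(ages$bias))

  # two identical groups give identical reports
  co2 <- co
  co2$gender <- rep(c("M", "F"), each = n / 2)
  co2$tau_est[co2$gender == "F"] <- co2$tau_est[co2$gender == "M"]
  co2$tau_true[co2$gender == "F"] <- co2$tau_true[co2$gender == "M"]
  t2 <- evaluate_by_group(co2, "tau_est", "tau_true", group_cols = "gender")
  m <- t2[t2$group == "M", -1]; f <- t2[t2$group == "F", -1]
  expect_equal(as.numeric(m[-1]), as.numeric(f[-1]))

  # small groups are skipped with a warning
  co3 <- co[1:5, ]; co3$gender <- c("M", "M", "M", "M", "F")
  expect_warning(evaluate_by_group(co3, "tau_est", "tau_true",
                                   group_cols = "gender"), "skipped")

  # construction with est slope above 1 overestimates in every group
  expect_true(all(tab$bias > 0))
})
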