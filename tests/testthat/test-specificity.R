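test_that("specificity ratios impute the detection limit for quiet off-targets", {
  lim <- detection_limit(30)
  r <- specificity_ratio(26.0, 0, limit = lim)
  expect_equal(r$ratio, 26.0 / 0.025)  # 1040
  expect_true(r$imputed)
  expect_true(r$lower_bound)
  expect_equal(r$off_percent_used, lim)

  r <- specificity_ratio(29.0, 1.1, limit = lim)
  expect_equal(r$ratio, 29.0 / 1.1, tolerance = 1e-12)
  expect_false(r$lower_bound)

  r <- specificity_ratio(0, 1, limit = lim)
  expect_false(r$defined)
  expect_true(is.na(r$ratio))
})

test_that("imputation keeps the ratio non-increasing in observed off-target editing", {
  lim <- detection_limit(30)
  offs <- c(0, 0.01, 0.025, 0.03, 0.1, 1, 5)
  ratios <- vapply(offs, function(o) specificity_ratio(20, o, lim)$ratio,
                   numeric(1))
  expect_true(all(diff(ratios) <= 0))
  flags <- vapply(offs, function(o) specificity_ratio(20, o, lim)$lower_bound,
                  logical(1))
  expect_identical(flags, offs <= lim)
})

test_that("fold changes reproduce the reported integer-fold labels", {
  f <- fold_change(1.1, 0.03)
  expect_equal(f$fold, 1.1 / 0.03, tolerance = 1e-12)  # 36.67 -> "37-fold"
  expect_identical(f$label, "37-fold")
  f <- fold_change(15, 5.0)
  expect_equal(f$fold, 3.0)
  expect_identical(f$label, "3-fold")
  expect_equal(fold_change(4.2, 4.2)$fold, 1.0)
  # zero denominator becomes a detection-limit lower bound
  f <- fold_change(2.5, 0)
  expect_true(f$lower_bound)
  expect_equal(f$fold, 2.5 / detection_limit(30))
})

test_that("reciprocal fold changes multiply to one", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.01, 50); b <- runif(1, 0.01, 50)
    expect_equal(fold_change(a, b)$fold * fold_change(b, a)$fold, 1,
                 tolerance = 1e-12)
  }
})

test_that("editing:indel ratios impute the limit for indel-free loci", {
  expect_equal(editing_indel_ratio(20, 2)$ratio, 10.0)
  r <- editing_indel_ratio(20, 0)
  expect_true(r$lower_bound)
  expect_equal(r$ratio, 20 / detection_limit(30))
  r <- editing_indel_ratio(NA_real_, 2)
  expect_false(r$defined)
})

test_that("dose-response regression recovers exact lines and flat nulls", {
  on <- c(1, 3, 5, 8, 12)
  fit <- fit_dose_response(on, 2 * on + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- fit_dose_response(on, rep(4.2, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)

  expect_error(fit_dose_response(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_dose_response(rep(1, 4), 1:4), "no variance")
})

test_that("regression matches the closed-form OLS oracle", {
  on <- c(2.0, 4.5, 7.1, 9.8, 14.2)
  off <- c(0.11, 0.24, 0.31, 0.56, 0.62)
  fit <- fit_dose_response(on, off)
  # closed forms
  n <- length(on)
  sxx <- sum((on - mean(on))^2)
  sxy <- sum((on - mean(on)) * (off - mean(off)))
  slope <- sxy / sxx
  intercept <- mean(off) - slope * mean(on)
  r2 <- sxy^2 / (sxx * sum((off - mean(off))^2))
  fstat <- (n - 2) * r2 / (1 - r2)
  p <- pf(fstat, 1, n - 2, lower.tail = FALSE)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit$f_statistic, fstat, tolerance = 1e-10)
  expect_equal(fit$p_value, p, tolerance = 1e-10)
})

test_that("R-squared is invariant to affine rescaling of the on-target axis", {
  set.seed(9)
  on <- runif(6, 1, 30)
  off <- 0.04 * on + rnorm(6, sd = 0.1)
  base <- fit_dose_response(on, off)$r_squared
  expect_equal(fit_dose_response(3.7 * on - 11, off)$r_squared, base,
               tolerance = 1e-12)
})

test_that("specificity improvements aggregate per-cytosine quotients", {
  lim <- detection_limit(30)
  a <- list(specificity_ratio(20, 0.1, lim), specificity_ratio(30, 0.2, lim))
  b <- list(specificity_ratio(20, 1.0, lim), specificity_ratio(30, 2.0, lim))
  imp <- specificity_improvement(a, b)
  expect_equal(imp$mean_of_ratios, 10)
  expect_equal(imp$ratio_of_means, (200 + 150) / (20 + 15))
  expect_false(imp$lower_bound)
  expect_identical(imp$method, "mean_of_ratios")
  # an imputed input marks the aggregate as a lower bound
  a[[1]] <- specificity_ratio(20, 0, lim)
  expect_true(specificity_improvement(a, b)$lower_bound)
})
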