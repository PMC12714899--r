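test_that("extra sum-of-squares F statistic follows the nested formula", {
  cmp <- extra_ss_f_test(list(ss_residual = 12, df = 21),
                         list(ss_residual = 10, df = 20))
  expect_equal(cmp$f_stat, 4)
  expect_equal(cmp$df_numerator, 1)
  expect_equal(cmp$df_denominator, 20)
  expect_equal(cmp$p_value, stats::pf(4, 1, 20, lower.tail = FALSE))
  expect_equal(round(cmp$p_value, 4), 0.0593)

  same <- extra_ss_f_test(list(ss_residual = 10, df = 21),
                          list(ss_residual = 10, df = 20))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)

  expect_error(extra_ss_f_test(list(ss_residual = 10, df = 20),
                               list(ss_residual = 9, df = 20)),
               class = "tgt_validation_error")
  expect_error(extra_ss_f_test(list(ss_residual = 10, df = 21),
                               list(ss_residual = 0, df = 20)),
               class = "tgt_degenerate_fit_error")
})

test_that("nested F test on module fits matches an independent grid oracle", {
  # ten-point toy groups; oracle refits both models by zoomed grid search
  set.seed(31)
  temps <- default_temps()[c(2, 4, 5, 6, 7, 8, 9, 10, 11, 13)]
  mk <- function(tp) {
    g <- exp(-(temps - tp)^2 / (2 * 9^2))
    data.frame(temp_c = temps, percent = 14 * g + rnorm(10, 0, 1.2))
  }
  a <- mk(29)
  b <- mk(33)
  cmp <- compare_preference(a, b, "t_peak")

  oa <- zoom_grid_fit(a$temp_c, a$percent)
  ob <- zoom_grid_fit(b$temp_c, b$percent)
  onull <- zoom_grid_fit_shared_tpeak(a$temp_c, a$percent, b$temp_c, b$percent)
  ss_alt <- oa$ss + ob$ss
  df_alt <- 20 - 6
  f_oracle <- ((onull$ss - ss_alt) / 1) / (ss_alt / df_alt)
  expect_lt(abs(cmp$f_stat - f_oracle), 1e-6)
  expect_equal(cmp$df_numerator, 1)
  expect_equal(cmp$df_denominator, 14)
})

test_that("null fits never beat the separate fits", {
  for (s in 1:5) {
    a <- noisy_points(t_peak = 30, seed = 60 + s)
    b <- noisy_points(t_peak = 33, seed = 600 + s)
    for (param in c("t_peak", "sd")) {
      cmp <- compare_preference(a, b, param)
      expect_gte(cmp$ss_null, cmp$ss_alt - 1e-9)
      expect_gte(cmp$f_stat, 0)
      expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
    }
  }
})

test_that("Welch t test matches hand-computed values", {
  res <- welch_t_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(res$statistic, -2.19089, tolerance = 1e-4)
  expect_equal(res$df, 6)
  # hand formula: t = -2 / sqrt(5/3 / 4 * 2); p from the t(6) tail
  expect_equal(res$p_value, 2 * stats::pt(-2 / sqrt(5 / 6), 6), tolerance = 1e-6)
  expect_equal(round(res$p_value, 2), 0.07)
  expect_equal(res$mean_difference, -2)

  ident <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  expect_error(welch_t_test(c(0, 0, 0), c(1, 1, 1)),
               class = "tgt_undefined_test_error")
  expect_error(welch_t_test(1, c(1, 2)), class = "tgt_validation_error")
})

test_that("Welch reduces to the pooled t test for equal n and variance", {
  set.seed(8)
  a <- rnorm(10)
  b <- a[sample(10)] + 0.5 # same variance, shifted
  w <- welch_t_test(a, b)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-9)
  expect_lte(w$df, 18)
})

test_that("paired t test works on differences", {
  before <- c(10, 20, 30)
  after <- before + c(1, 2, 3)
  res <- paired_t_test(after, before) # differences 1, 2, 3
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  flipped <- paired_t_test(before, after)
  expect_equal(abs(flipped$statistic), abs(res$statistic), tolerance = 1e-12)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-12)

  expect_error(paired_t_test(before, before), class = "tgt_undefined_test_error")
  expect_error(paired_t_test(1:3, 1:4), class = "tgt_validation_error")
})

test_that("Cohen's d uses the pooled residual SD", {
  es <- cohens_d(1.5, 72, 50, 72, 50)
  expect_equal(es$pooled_sigma, 1.2)
  expect_equal(es$d, 1.25)

  expect_equal(cohens_d(0, 72, 50, 72, 50)$d, 0)

  # doubling both SS scales sigma by sqrt(2) and d by 1/sqrt(2)
  es2 <- cohens_d(1.5, 144, 50, 144, 50)
  expect_equal(es2$pooled_sigma, 1.2 * sqrt(2))
  expect_equal(es2$d, 1.25 / sqrt(2))

  expect_error(cohens_d(1, 0, 10, 0, 10), class = "tgt_degenerate_fit_error")
  expect_error(cohens_d(1, 5, 0, 5, 0), class = "tgt_validation_error")
})

test_that("sample size planning reproduces the published design numbers", {
  expect_equal(sample_size_per_group(1.5 / 1.2), 11L)
  expect_equal(sample_size_per_group(2.0 / 1.2), 6L)
  expect_equal(sample_size_per_group(0.625), 41L)

  # accepts an effect_size object
  expect_equal(sample_size_per_group(cohens_d(1.5, 72, 50, 72, 50)), 11L)

  # monotone in |d| and in target power
  ds <- c(0.4, 0.8, 1.2, 1.6)
  ns <- sapply(ds, sample_size_per_group)
  expect_true(all(diff(ns) < 0))
  expect_gte(sample_size_per_group(1.25, power = 0.9),
             sample_size_per_group(1.25, power = 0.8))

  # exact noncentral-t method is at least as demanding
  for (d in c(0.8, 1.25, 1.667))
    expect_gte(sample_size_per_group(d, method = "noncentral_t"),
               sample_size_per_group(d))

  huge <- sample_size_per_group(50)
  expect_equal(as.integer(huge), 2L)
  expect_true(isTRUE(attr(huge, "floored")))

  expect_error(sample_size_per_group(0), class = "tgt_config_error")
})
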