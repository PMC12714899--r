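#' Extra sum-of-squares F test on nested fits
#'
#' Compares a constrained (null) fit against a less constrained (alternative)
#' fit of the same points:
#' `F = ((SS_null - SS_alt) / (df_null - df_alt)) / (SS_alt / df_alt)`,
#' with the p-value from the upper tail of the F distribution on
#' `(df_null - df_alt, df_alt)` degrees of freedom. Tiny negative SS
#' differences from optimizer round-off are clamped to zero.
#'
#' @param fit_null,fit_alt Objects carrying `ss_residual` and `df` (e.g. a
#'   [fit_preference()] result, the shared-parameter fit inside
#'   [compare_preference()], or a plain `list(ss_residual =, df =)`).
#' @return A `nested_fit_comparison` with the SS/df pairs, `f_stat`,
#'   `df_numerator`, `df_denominator` and `p_value`.
#' @export
extra_ss_f_test <- function(fit_null, fit_alt) {
  ss0 <- fit_null$ss_residual
  df0 <- fit_null$df
  ss1 <- fit_alt$ss_residual
  df1 <- fit_alt$df
  if (is.null(ss0) || is.null(ss1) || is.null(df0) || is.null(df1))
    tgt_abort("fits must carry `ss_residual` and `df`", "tgt_validation_error")
  if (df0 <= df1)
    tgt_abort("models are not nested: null df must exceed alternative df",
              "tgt_validation_error")
  if (ss1 <= 0)
    tgt_abort("alternative fit has zero residual SS; F test undefined",
              "tgt_degenerate_fit_error")
  f <- max(0, (ss0 - ss1) / (df0 - df1) / (ss1 / df1))
  structure(list(ss_null = ss0, df_null = df0, ss_alt = ss1, df_alt = df1,
                 f_stat = f, df_numerator = df0 - df1, df_denominator = df1,
                 p_value = stats::pf(f, df0 - df1, df1, lower.tail = FALSE)),
            class = "nested_fit_comparison")
}

#' @export
print.nested_fit_comparison <- function(x, ...) {
  cat(sprintf("Extra sum-of-squares F test: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_numerator, x$df_denominator, x$f_stat, x$p_value))
  invisible(x)
}

#' Compare a preference parameter between two groups
#'
#' Fits the two groups' pooled occupancy points separately (alternative
#' model) and jointly with the tested parameter shared (null model), then
#' applies the extra sum-of-squares F test. Only the parameter under test is
#' constrained; the other center/width parameter and any amplitude stay
#' group-specific, so the comparison has one numerator degree of freedom.
#'
#' @param points_a,points_b Data frames with `temp_c` and `percent` (see
#'   [occupancy_points()]), or lists of occupancy profiles.
#' @param parameter `"t_peak"` or `"sd"`.
#' @param amplitude_mode Passed to [fit_preference()].
#' @return A `nested_fit_comparison` with the per-group fits attached as
#'   `fit_a` and `fit_b` and the tested parameter as `parameter`.
#' @export
compare_preference <- function(points_a, points_b,
                               parameter = c("t_peak", "sd"),
                               amplitude_mode = c("free_3p", "normalized_2p")) {
  parameter <- match.arg(parameter)
  amplitude_mode <- match.arg(amplitude_mode)
  as_points <- function(p) {
    if (is.list(p) && !is.data.frame(p) &&
        all(vapply(p, inherits, TRUE, "occupancy_profile")))
      occupancy_points(p) else p
  }
  points_a <- as_points(points_a)
  points_b <- as_points(points_b)
  fa <- fit_preference(points_a, amplitude_mode)
  fb <- fit_preference(points_b, amplitude_mode)
  alt <- list(ss_residual = fa$ss_residual + fb$ss_residual,
              df = fa$df + fb$df)
  null <- fit_preference_shared(points_a, points_b, shared = parameter,
                                amplitude_mode = amplitude_mode)
  cmp <- extra_ss_f_test(null, alt)
  cmp$parameter <- parameter
  cmp$fit_a <- fa
  cmp$fit_b <- fb
  cmp
}

#' Welch's two-sample t test (heteroscedastic, two-tailed)
#'
#' @param a,b Numeric samples, each with `n >= 2`; at least one must have
#'   nonzero variance.
#' @return A `t_test_result` with `statistic`, `df` (Welch-Satterthwaite,
#'   possibly fractional), two-tailed `p_value`, `mean_difference` and
#'   `test_kind`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    tgt_abort("each sample needs n >= 2", "tgt_validation_error")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    tgt_abort("both samples have zero variance; t test undefined",
              "tgt_undefined_test_error")
  res <- stats::t.test(a, b, var.equal = FALSE, paired = FALSE)
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 mean_difference = mean(a) - mean(b),
                 test_kind = "welch"),
            class = "t_test_result")
}

#' Paired t test (two-tailed)
#'
#' @param before,after Paired samples of equal length `>= 2` whose
#'   differences have nonzero variance.
#' @return A `t_test_result` with `df = n - 1`.
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after))
    tgt_abort("paired samples must have equal length", "tgt_validation_error")
  if (length(before) < 2)
    tgt_abort("need at least 2 pairs", "tgt_validation_error")
  if (stats::var(after - before) == 0)
    tgt_abort("paired differences have zero variance; t test undefined",
              "tgt_undefined_test_error")
  res <- stats::t.test(before, after, paired = TRUE)
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value,
                 mean_difference = mean(before) - mean(after),
                 test_kind = "paired"),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4g, df = %.4g, p = %.4g (mean diff %.4g)\n",
              x$test_kind, x$statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' Cohen's d from residual sums of squares
#'
#' Standardized effect size `d = delta_mu / sigma` with the pooled residual
#' standard deviation `sigma = sqrt((SS_a + SS_b) / (DFd_a + DFd_b))`, where
#' SS and DFd are the residual sum of squares and degrees of freedom of the
#' two group fits. Note that a pooled sigma taken from nonlinear model
#' residuals omits between-subject variance and can overstate d; treat the
#' resulting sample sizes as lower bounds.
#'
#' @param delta_mu Detectable mean difference, in the variable's units.
#' @param ss_a,ss_b Residual sums of squares.
#' @param dfd_a,dfd_b Residual degrees of freedom.
#' @return An `effect_size` with `delta_mu`, `pooled_sigma` and `d`.
#' @examples
#' cohens_d(1.5, 72, 50, 72, 50) # pooled sigma 1.2, d = 1.25
#' @export
cohens_d <- function(delta_mu, ss_a, dfd_a, ss_b, dfd_b) {
  if (dfd_a + dfd_b <= 0)
    tgt_abort("total residual df must be positive", "tgt_validation_error")
  if (ss_a < 0 || ss_b < 0)
    tgt_abort("sums of squares must be >= 0", "tgt_validation_error")
  sigma <- sqrt((ss_a + ss_b) / (dfd_a + dfd_b))
  if (sigma <= 0)
    tgt_abort("pooled variance is zero; d undefined", "tgt_degenerate_fit_error")
  structure(list(delta_mu = delta_mu, pooled_sigma = sigma,
                 d = delta_mu / sigma),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Effect size: delta = %.3g, pooled sigma = %.3g, d = %.3g\n",
              x$delta_mu, x$pooled_sigma, x$d))
  invisible(x)
}

#' Per-group sample size for a two-sample comparison
#'
#' Default `normal_approx`:
#' `n = ceiling(2 * (z_(1-alpha/2) + z_power)^2 / d^2)`, the standard normal
#' approximation for a two-sided two-sample t comparison. The
#' `noncentral_t` method instead searches for the smallest n whose exact
#' noncentral-t power reaches the target (via [stats::power.t.test()]); it
#' returns values at least as large as the approximation.
#'
#' @param d Cohen's d (or an `effect_size` object); must be nonzero.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param method `"normal_approx"` or `"noncentral_t"`.
#' @return Integer n per group; floored at 2 (with attribute
#'   `floored = TRUE` when the formula gave less).
#' @examples
#' sample_size_per_group(1.5 / 1.2) # 11
#' sample_size_per_group(2.0 / 1.2) # 6
#' @export
sample_size_per_group <- function(d, alpha = 0.05, power = 0.80,
                                  method = c("normal_approx", "noncentral_t")) {
  method <- match.arg(method)
  if (inherits(d, "effect_size")) d <- d$d
  if (!is_number(d) || d == 0)
    tgt_abort("`d` must be a nonzero number", "tgt_config_error")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    tgt_abort("`alpha` and `power` must lie in (0, 1)", "tgt_config_error")
  n <- if (method == "normal_approx") {
    z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
    ceiling(2 * z^2 / d^2)
  } else {
    ceiling(stats::power.t.test(delta = abs(d), sd = 1, sig.level = alpha,
                                power = power, type = "two.sample",
                                alternative = "two.sided")$n)
  }
  n <- as.integer(n)
  if (n < 2L) {
    n <- 2L
    attr(n, "floored") <- TRUE
  }
  n
}
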