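#' Gaussian temperature-preference model
#'
#' Occupancy as a function of zone-center temperature is modeled as a
#' Gaussian bump centered at the most preferred temperature `t_peak_c` with
#' width `sd_c`. Two amplitude conventions are supported:
#' \describe{
#'   \item{normalized_2p}{Two free parameters; predicted zone values are
#'     normalized to sum to exactly 100, so peak occupancy is a dependent
#'     variable of the width (a narrower distribution has a taller peak).}
#'   \item{free_3p}{Three free parameters; the amplitude multiplies the unit
#'     Gaussian directly. This is the default for fitting and for nested
#'     model comparisons.}
#' }
#'
#' @param t_peak_c Center, degrees C.
#' @param sd_c Width (SD), degrees C; > 0.
#' @param amplitude_mode `"normalized_2p"` or `"free_3p"`.
#' @param amplitude Percent; required in `free_3p` mode, derived otherwise.
#' @return A `gaussian_preference_model`.
#' @export
gaussian_preference_model <- function(t_peak_c, sd_c,
                                      amplitude_mode = c("normalized_2p", "free_3p"),
                                      amplitude = NULL) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is_number(sd_c) || sd_c <= 0)
    tgt_abort("`sd_c` must be > 0", "tgt_config_error")
  if (amplitude_mode == "free_3p" && !is_number(amplitude %||% NA_real_))
    tgt_abort("free_3p mode needs an `amplitude`", "tgt_config_error")
  structure(list(t_peak_c = t_peak_c, sd_c = sd_c,
                 amplitude_mode = amplitude_mode, amplitude = amplitude),
            class = "gaussian_preference_model")
}

#' Predicted zone occupancies under a preference model
#'
#' @param model A [gaussian_preference_model()].
#' @param temps Temperatures at which to evaluate, degrees C; defaults to
#'   the standard zone centers.
#' @return Percent values; in `normalized_2p` mode they sum to exactly 100
#'   over the supplied temperatures.
#' @export
predict_occupancy <- function(model, temps = zone_center_temps()) {
  if (model$sd_c <= 0) tgt_abort("`sd_c` must be > 0", "tgt_config_error")
  g <- exp(-(temps - model$t_peak_c)^2 / (2 * model$sd_c^2))
  if (model$amplitude_mode == "normalized_2p") 100 * g / sum(g)
  else model$amplitude * g
}

#' Peak zone occupancy implied by a preference width
#'
#' Maximum of the normalized two-parameter model over the zone temperatures.
#' In the wide-SD limit it approaches the uniform benchmark 100/14 = 7.14%;
#' for a narrow preference centered on a zone it approaches 100%.
#'
#' @param sd_c Preference width, degrees C.
#' @param zone_temps Zone-center temperatures.
#' @param t_peak_c Preference center, degrees C.
#' @return Percent.
#' @export
peak_occupancy_of <- function(sd_c, zone_temps = zone_center_temps(),
                              t_peak_c = 31) {
  max(predict_occupancy(
    gaussian_preference_model(t_peak_c, sd_c, "normalized_2p"), zone_temps))
}

# --- internal fitting machinery -------------------------------------------

# Aggregate pooled (temp, percent) points by unique temperature: every sum
# the objective needs reduces to O(n_temps) regardless of how many animals
# are pooled.
agg_points <- function(temp, percent) {
  u <- sort(unique(temp))
  key <- match(temp, u)
  list(u = u,
       s1 = as.numeric(tapply(percent, key, sum)),
       m = as.numeric(tabulate(key, nbins = length(u))),
       sumy2 = sum(percent^2),
       n = length(percent))
}

# residual SS at (t_peak, sd); free_3p profiles the amplitude out in closed
# form (variable projection): A = sum(g*y) / sum(g^2)
gauss_ss <- function(t_peak, sd, agg, mode) {
  g <- exp(-(agg$u - t_peak)^2 / (2 * sd^2))
  if (mode == "free_3p") {
    den <- sum(agg$m * g^2)
    if (den <= 0) return(agg$sumy2)
    agg$sumy2 - sum(g * agg$s1)^2 / den
  } else {
    p <- 100 * g / sum(g)
    agg$sumy2 - 2 * sum(p * agg$s1) + sum(agg$m * p^2)
  }
}

varpro_amplitude <- function(t_peak, sd, agg) {
  g <- exp(-(agg$u - t_peak)^2 / (2 * sd^2))
  sum(g * agg$s1) / sum(agg$m * g^2)
}

# Vectorized SS over a (t_peak, sd) grid. Grids are ordered sd-major with
# t_peak fastest so which.min's first-hit tie-break lands on the smallest sd,
# then the smallest t_peak.
grid_ss <- function(tp_seq, sd_seq, agg, mode) {
  combos <- expand.grid(t_peak = tp_seq, sd = sd_seq,
                        KEEP.OUT.ATTRS = FALSE)
  D2 <- outer(combos$t_peak, agg$u, "-")^2
  G <- exp(-D2 / (2 * combos$sd^2)) # recycles per-row: sd varies by row
  if (mode == "free_3p") {
    num <- as.numeric(G %*% agg$s1)
    den <- as.numeric((G * G) %*% agg$m)
    ss <- agg$sumy2 - ifelse(den > 0, num^2 / den, 0)
  } else {
    P <- 100 * G / rowSums(G)
    ss <- agg$sumy2 - 2 * as.numeric(P %*% agg$s1) +
      as.numeric((P * P) %*% agg$m)
  }
  list(combos = combos, ss = ss)
}

default_grid <- function() {
  list(tp = seq(4, 58, by = 0.5), sd = seq(0.5, 40, by = 0.5),
       tp_box = c(4, 58), sd_box = c(0.5, 40))
}

#' Fit the Gaussian preference model to pooled occupancy points
#'
#' Least squares over pooled per-animal, per-zone points. The fit is a coarse
#' grid search over the center/width box (center 4-58 C, width 0.5-40 C, both
#' at 0.5 C steps; grid ties broken toward smaller width, then smaller
#' center) followed by box-constrained quasi-Newton refinement; in `free_3p`
#' mode the amplitude is profiled out in closed form at every evaluation
#' (variable projection). Standard errors come from the Gauss-Newton
#' approximation at the optimum. Near-flat data whose fitted width lands at
#' the upper box edge are flagged `"flat_preference"` rather than reported as
#' a spurious peak.
#'
#' @param points Data frame with columns `temp_c` and `percent` (e.g. from
#'   [occupancy_points()]), or a list of occupancy profiles.
#' @param amplitude_mode `"free_3p"` (default) or `"normalized_2p"`.
#' @return A `gaussian_fit` with the fitted `model`, `ss_residual`, `df`
#'   (`n_points` minus 2 or 3), `n_points`, `peak_occupancy_percent` (model
#'   value at the zone temperature nearest the fitted center), `se_t_peak`,
#'   `se_sd`, `converged` and `flags`.
#' @export
fit_preference <- function(points, amplitude_mode = c("free_3p", "normalized_2p")) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, TRUE, "occupancy_profile")))
    points <- occupancy_points(points)
  if (!all(c("temp_c", "percent") %in% names(points)))
    tgt_abort("`points` needs columns temp_c and percent", "tgt_schema_error")
  n_par <- if (amplitude_mode == "free_3p") 3L else 2L
  if (nrow(points) < n_par + 1L)
    tgt_abort("too few points for the requested model", "tgt_degenerate_input_error")
  if (length(unique(points$temp_c)) < 2L)
    tgt_abort("temperatures must span >= 2 distinct values",
              "tgt_degenerate_input_error")

  agg <- agg_points(points$temp_c, points$percent)
  grid <- default_grid()
  g <- grid_ss(grid$tp, grid$sd, agg, amplitude_mode)
  i0 <- which.min(g$ss)
  start <- c(g$combos$t_peak[i0], g$combos$sd[i0])

  obj <- function(p) gauss_ss(p[1], p[2], agg, amplitude_mode)
  opt <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B",
                 lower = c(grid$tp_box[1], grid$sd_box[1]),
                 upper = c(grid$tp_box[2], grid$sd_box[2]),
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL)

  flags <- character(0)
  if (!is.null(opt) && opt$value <= g$ss[i0] + 1e-12) {
    par <- opt$par
    ss <- opt$value
    converged <- opt$convergence == 0
    if (!converged) flags <- c(flags, "refinement_not_converged")
  } else {
    par <- start
    ss <- g$ss[i0]
    converged <- FALSE
    flags <- c(flags, "refinement_failed_grid_point_reported")
  }
  if (par[2] >= grid$sd_box[2] - 0.5) flags <- c(flags, "flat_preference")
  ss <- max(0, ss) # guard against round-off in the aggregated SS formula

  amplitude <- if (amplitude_mode == "free_3p")
    varpro_amplitude(par[1], par[2], agg) else NULL
  model <- gaussian_preference_model(par[1], par[2], amplitude_mode, amplitude)
  df <- agg$n - n_par

  se <- fit_standard_errors(model, points, ss, df)
  nearest <- agg$u[which.min(abs(agg$u - par[1]))]
  peak <- predict_occupancy(model, agg$u)[which.min(abs(agg$u - par[1]))]

  structure(list(model = model, ss_residual = ss, df = df,
                 n_points = agg$n,
                 peak_occupancy_percent = unname(peak),
                 peak_zone_temp_c = nearest,
                 converged = converged,
                 se_t_peak = se[1], se_sd = se[2], flags = flags),
            class = "gaussian_fit")
}

# Gauss-Newton standard errors via a numeric Jacobian of the per-point
# predictions with respect to the free parameters.
fit_standard_errors <- function(model, points, ss, df) {
  if (df < 1) return(c(NA_real_, NA_real_))
  u <- sort(unique(points$temp_c))
  pred_fun <- function(p) {
    m <- model
    m$t_peak_c <- p[1]
    m$sd_c <- p[2]
    if (model$amplitude_mode == "free_3p") m$amplitude <- p[3]
    vals <- predict_occupancy(m, u)
    vals[match(points$temp_c, u)]
  }
  p0 <- c(model$t_peak_c, model$sd_c,
          if (model$amplitude_mode == "free_3p") model$amplitude)
  J <- vapply(seq_along(p0), function(j) {
    h <- 1e-6 * max(1, abs(p0[j]))
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    (pred_fun(pp) - pred_fun(pm)) / (2 * h)
  }, numeric(nrow(points)))
  covm <- tryCatch(ss / df * chol2inv(chol(crossprod(J))),
                   error = function(e) NULL)
  if (is.null(covm)) return(c(NA_real_, NA_real_))
  sqrt(pmax(diag(covm)[1:2], 0))
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian preference fit (%s): T_peak = %.2f +/- %.2f C, SD = %.2f +/- %.2f C\n",
              x$model$amplitude_mode, x$model$t_peak_c, x$se_t_peak,
              x$model$sd_c, x$se_sd))
  cat(sprintf("  peak occupancy %.1f%%; SS = %.3f on %d df (n = %d)%s\n",
              x$peak_occupancy_percent, x$ss_residual, x$df, x$n_points,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Serialize a fit to the report JSON structure
#'
#' @param fit A `gaussian_fit`.
#' @param condition Optional condition label.
#' @return A named list ready for `jsonlite::write_json`.
#' @export
fit_report <- function(fit, condition = NA_character_) {
  list(condition = condition,
       amplitude_mode = fit$model$amplitude_mode,
       t_peak_c = fit$model$t_peak_c, se_t_peak = fit$se_t_peak,
       sd_c = fit$model$sd_c, se_sd = fit$se_sd,
       amplitude = fit$model$amplitude %||% NA_real_,
       peak_occupancy_percent = fit$peak_occupancy_percent,
       ss_residual = fit$ss_residual, df = fit$df, n_points = fit$n_points,
       converged = fit$converged, flags = as.list(fit$flags))
}

# Joint fit of two groups with one parameter shared (the null model of the
# extra sum-of-squares F test). Coarse profiling over the shared parameter,
# then joint refinement.
fit_preference_shared <- function(points_a, points_b,
                                  shared = c("t_peak", "sd"),
                                  amplitude_mode = c("free_3p", "normalized_2p")) {
  shared <- match.arg(shared)
  amplitude_mode <- match.arg(amplitude_mode)
  agg_a <- agg_points(points_a$temp_c, points_a$percent)
  agg_b <- agg_points(points_b$temp_c, points_b$percent)
  grid <- default_grid()
  ga <- grid_ss(grid$tp, grid$sd, agg_a, amplitude_mode)
  gb <- grid_ss(grid$tp, grid$sd, agg_b, amplitude_mode)
  n_tp <- length(grid$tp)
  Ma <- matrix(ga$ss, nrow = n_tp) # rows t_peak, cols sd
  Mb <- matrix(gb$ss, nrow = n_tp)

  if (shared == "t_peak") {
    prof <- apply(Ma, 1, min) + apply(Mb, 1, min)
    i <- which.min(prof)
    start <- c(grid$tp[i],
               grid$sd[which.min(Ma[i, ])], grid$sd[which.min(Mb[i, ])])
    obj <- function(p) gauss_ss(p[1], p[2], agg_a, amplitude_mode) +
      gauss_ss(p[1], p[3], agg_b, amplitude_mode)
    lower <- c(grid$tp_box[1], grid$sd_box[1], grid$sd_box[1])
    upper <- c(grid$tp_box[2], grid$sd_box[2], grid$sd_box[2])
  } else {
    prof <- apply(Ma, 2, min) + apply(Mb, 2, min)
    j <- which.min(prof)
    start <- c(grid$sd[j],
               grid$tp[which.min(Ma[, j])], grid$tp[which.min(Mb[, j])])
    obj <- function(p) gauss_ss(p[2], p[1], agg_a, amplitude_mode) +
      gauss_ss(p[3], p[1], agg_b, amplitude_mode)
    lower <- c(grid$sd_box[1], grid$tp_box[1], grid$tp_box[1])
    upper <- c(grid$sd_box[2], grid$tp_box[2], grid$tp_box[2])
  }
  opt <- tryCatch(
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL)
  ss0 <- min(prof)
  if (!is.null(opt) && opt$value <= ss0) {
    ss <- opt$value
    par <- opt$par
  } else {
    ss <- ss0
    par <- start
  }
  per_group <- if (amplitude_mode == "free_3p") 3L else 2L
  n <- agg_a$n + agg_b$n
  list(shared = shared, par = par, ss_residual = ss,
       df = n - (2L * per_group - 1L), n_points = n,
       amplitude_mode = amplitude_mode)
}
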