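#' Corridor geometry for the thermal gradient test
#'
#' The assay arena is a long corridor whose floor carries a linear thermal
#' gradient along its length. Positions are measured in cm from the cold end
#' (`x = 0`); the corridor is partitioned into `n_zones` equal-width zones,
#' numbered 1 (cold end) to `n_zones` (hot end). The defaults describe a
#' 137 cm corridor divided into 14 zones of 9.8 cm, roughly the effective
#' body length of a moving mouse.
#'
#' @param length_cm Corridor length in cm along the gradient axis.
#' @param width_cm Corridor width in cm (not used in 1-D analyses; kept for
#'   provenance).
#' @param n_zones Number of equal-width zones.
#' @return An object of class `arena_geometry` with fields `length_cm`,
#'   `width_cm`, `n_zones` and the derived `zone_width_cm`.
#' @examples
#' a <- arena_geometry()
#' round(a$zone_width_cm, 1) # 9.8
#' @export
arena_geometry <- function(length_cm = 137, width_cm = 10, n_zones = 14) {
  if (!is_number(length_cm) || length_cm <= 0)
    tgt_abort("`length_cm` must be a positive number", "tgt_config_error")
  if (!is_number(width_cm) || width_cm <= 0)
    tgt_abort("`width_cm` must be a positive number", "tgt_config_error")
  if (!is_count(n_zones))
    tgt_abort("`n_zones` must be a positive integer", "tgt_config_error")
  structure(
    list(length_cm = length_cm, width_cm = width_cm,
         n_zones = as.integer(n_zones),
         zone_width_cm = length_cm / n_zones),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("TGT arena: %.1f x %.1f cm, %d zones of %.2f cm\n",
              x$length_cm, x$width_cm, x$n_zones, x$zone_width_cm))
  invisible(x)
}

#' Linear position-to-temperature calibration
#'
#' Maps position `x` (cm from the cold end) to floor surface temperature via
#' `temp = slope * x + intercept`. The nominal calibration is the endpoint
#' line of the apparatus: 4 degrees C at the cold end and 58 degrees C at the
#' hot end (slope 54/137, about 0.394 C/cm). A fitted calibration from
#' thermocouple measurements (see [fit_calibration()]) can replace it.
#'
#' @param slope Degrees C per cm; must be positive (temperature increases
#'   toward the hot end).
#' @param intercept Degrees C at `x = 0` (the cold end).
#' @param r_squared Coefficient of determination of the calibration fit
#'   (1 for a nominal two-point line).
#' @param source `"nominal"` or `"fitted"`.
#' @return An object of class `thermal_calibration`.
#' @export
thermal_calibration <- function(slope, intercept, r_squared = NA_real_,
                                source = c("nominal", "fitted")) {
  source <- match.arg(source)
  if (!is_number(slope) || slope <= 0)
    tgt_abort("calibration `slope` must be positive", "tgt_config_error")
  if (!is_number(intercept))
    tgt_abort("calibration `intercept` must be a number", "tgt_config_error")
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = r_squared, source = source),
    class = "thermal_calibration"
  )
}

#' @rdname thermal_calibration
#' @param cold_c,hot_c Endpoint temperatures of the nominal gradient.
#' @param arena Arena geometry giving the corridor length.
#' @export
nominal_calibration <- function(cold_c = 4, hot_c = 58, arena = arena_geometry()) {
  if (hot_c <= cold_c)
    tgt_abort("`hot_c` must exceed `cold_c`", "tgt_config_error")
  thermal_calibration(slope = (hot_c - cold_c) / arena$length_cm,
                      intercept = cold_c, r_squared = 1, source = "nominal")
}

#' @export
print.thermal_calibration <- function(x, ...) {
  cat(sprintf("Thermal calibration (%s): T = %.4f * x + %.2f", x$source,
              x$slope, x$intercept))
  if (is.finite(x$r_squared)) cat(sprintf("  (R^2 = %.3f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Zone index of a position
#'
#' Zones are half-open intervals `[lo, hi)` of width `length_cm / n_zones`,
#' lower-inclusive, except the final zone which is closed at the corridor end
#' so the partition covers the whole arena without double counting.
#'
#' @param x_cm Position(s) in cm from the cold end; vectorized.
#' @param arena An [arena_geometry()].
#' @return Integer zone indices, 1 (cold end) to `n_zones` (hot end).
#' @examples
#' zone_of_position(c(0, 68.5, 137), arena_geometry()) # 1, 8, 14
#' @export
zone_of_position <- function(x_cm, arena = arena_geometry()) {
  if (!is.numeric(x_cm) || anyNA(x_cm))
    tgt_abort("positions must be numeric and non-missing", "tgt_validation_error")
  bad <- x_cm < 0 | x_cm > arena$length_cm
  if (any(bad))
    tgt_abort(sprintf("position(s) outside the arena [0, %g]: %s",
                      arena$length_cm,
                      paste(utils::head(x_cm[bad], 5), collapse = ", ")),
              "tgt_out_of_arena_error")
  # floor on the normalized coordinate keeps exact zone boundaries exact
  z <- floor((x_cm / arena$length_cm) * arena$n_zones) + 1L
  pmin.int(as.integer(z), arena$n_zones)
}

#' Temperature at a position under a calibration
#'
#' @param x_cm Position(s) in cm; must lie within the arena.
#' @param calib A [thermal_calibration()].
#' @param arena Arena used for the bounds check.
#' @return Temperature(s) in degrees C.
#' @export
temperature_at_position <- function(x_cm, calib = nominal_calibration(),
                                    arena = arena_geometry()) {
  if (any(x_cm < 0 | x_cm > arena$length_cm))
    tgt_abort("position outside the arena", "tgt_out_of_arena_error")
  calib$slope * x_cm + calib$intercept
}

#' Zone-center temperatures
#'
#' Temperatures at the midpoints of the zones; the abscissa for occupancy
#' profiles and Gaussian preference fits.
#'
#' @inheritParams temperature_at_position
#' @return Numeric vector of length `n_zones`, cold to hot.
#' @export
zone_center_temps <- function(arena = arena_geometry(),
                              calib = nominal_calibration()) {
  mids <- (seq_len(arena$n_zones) - 0.5) * arena$zone_width_cm
  temperature_at_position(mids, calib, arena)
}

#' Fit a thermal calibration from thermocouple measurements
#'
#' Ordinary least squares of measured surface temperature on position along
#' the corridor. Requires at least two distinct positions. For a zero-variance
#' response (all temperatures identical) the coefficient of determination is
#' reported as 0 by convention rather than NaN.
#'
#' @param points Data frame with columns `x_cm` and `temp_c`.
#' @param arena Arena used to validate positions.
#' @return A `thermal_calibration` with `source = "fitted"`.
#' @examples
#' fit_calibration(data.frame(x_cm = c(0, 137), temp_c = c(4, 58)))
#' @export
fit_calibration <- function(points, arena = arena_geometry()) {
  if (!is.data.frame(points) || !all(c("x_cm", "temp_c") %in% names(points)))
    tgt_abort("`points` must be a data frame with columns x_cm and temp_c",
              "tgt_schema_error")
  if (any(points$x_cm < 0 | points$x_cm > arena$length_cm))
    tgt_abort("calibration point outside the arena", "tgt_out_of_arena_error")
  if (length(unique(points$x_cm)) < 2L)
    tgt_abort("need measurements at >= 2 distinct positions",
              "tgt_degenerate_input_error")
  fit <- stats::lm(temp_c ~ x_cm, data = points)
  co <- stats::coef(fit)
  ss_tot <- sum((points$temp_c - mean(points$temp_c))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  slope <- unname(co["x_cm"])
  if (slope <= 0) {
    # flat or inverted measurements: keep the result inspectable instead of
    # refusing, but it cannot be used as a gradient calibration downstream
    return(structure(
      list(slope = slope, intercept = unname(co["(Intercept)"]),
           r_squared = r2, source = "fitted"),
      class = "thermal_calibration"))
  }
  thermal_calibration(slope = slope, intercept = unname(co["(Intercept)"]),
                      r_squared = r2, source = "fitted")
}

#' Temperature resolution of a linear gradient
#'
#' `(hot - cold) / length`: the change in floor temperature per cm of
#' corridor. For the default apparatus, (58 - 4) / 137 = 0.39 C/cm.
#'
#' @param cold_c,hot_c Endpoint temperatures in degrees C.
#' @param length_cm Corridor length in cm.
#' @return Degrees C per cm.
#' @export
gradient_resolution <- function(cold_c = 4, hot_c = 58, length_cm = 137) {
  if (!is_number(length_cm) || length_cm <= 0)
    tgt_abort("`length_cm` must be positive", "tgt_degenerate_input_error")
  if (hot_c <= cold_c)
    tgt_abort("`hot_c` must exceed `cold_c`", "tgt_config_error")
  (hot_c - cold_c) / length_cm
}
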