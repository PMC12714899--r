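#' Configuration for the thermotaxis simulator
#'
#' The simulator is a discrete-time Ornstein-Uhlenbeck (OU) drift-diffusion
#' on the corridor: while moving, position drifts toward the preferred
#' position at rate `attraction_rate_per_s` (k) and diffuses with a noise
#' amplitude chosen so the unreflected stationary law is Gaussian with
#' temperature SD `sd_pref_c` — exactly the distribution family the assay
#' fits. Paths reflect at the corridor ends. Rest bouts freeze the position:
#' they are entered with per-second hazard `rest_hazard_per_s` weighted by a
#' Gaussian factor in temperature (resting concentrates in preferred zones)
#' and last exponentially distributed times with mean `rest_mean_s`.
#'
#' `locomotion_scale` rescales time for the movement process (noise amplitude
#' by the scale, attraction rate by its square), so locomotor speed changes
#' while the stationary preference distribution is untouched.
#'
#' When `attraction_rate_per_s` is 0 the process has no thermal drift; the
#' diffusion amplitude then falls back to `diffusion_cm_per_sqrt_s` (times
#' `locomotion_scale`) and the stationary law on the reflected interval is
#' uniform.
#'
#' @param t_pref_c Preferred temperature, degrees C.
#' @param sd_pref_c Preference width (temperature SD), degrees C; > 0.
#' @param attraction_rate_per_s OU mean-reversion rate k, 1/s; >= 0.
#' @param locomotion_scale Unitless time-rescaling of the movement process.
#' @param rest_hazard_per_s Baseline hazard of entering a rest bout, 1/s.
#' @param rest_mean_s Mean rest-bout duration, s.
#' @param duration_s,fps Recording length and frame rate.
#' @param n_animals Cohort size for [simulate_cohort()].
#' @param seed Integer seed; per-animal seeds are derived from it.
#' @param start_mode `"center"` (animals are placed mid-gradient, as in the
#'   assay), `"random"`, or `"preferred"` (start at the preferred position).
#' @param diffusion_cm_per_sqrt_s Diffusion amplitude used when k = 0.
#' @param end_bias_rate_per_s Drift rate toward the nearest corridor end;
#'   models the corner-seeking habit seen without a gradient. Usually 0.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(t_pref_c = 30.4, sd_pref_c = 11.6,
                              attraction_rate_per_s = 0.2,
                              locomotion_scale = 1,
                              rest_hazard_per_s = 0.05, rest_mean_s = 6,
                              duration_s = 600, fps = 15, n_animals = 12,
                              seed = 1L,
                              start_mode = c("center", "random", "preferred"),
                              diffusion_cm_per_sqrt_s = 15,
                              end_bias_rate_per_s = 0) {
  start_mode <- match.arg(start_mode)
  if (sd_pref_c <= 0) tgt_abort("`sd_pref_c` must be > 0", "tgt_config_error")
  if (fps <= 0 || duration_s <= 0)
    tgt_abort("`fps` and `duration_s` must be > 0", "tgt_config_error")
  if (attraction_rate_per_s < 0)
    tgt_abort("`attraction_rate_per_s` must be >= 0", "tgt_config_error")
  structure(list(
    t_pref_c = t_pref_c, sd_pref_c = sd_pref_c,
    attraction_rate_per_s = attraction_rate_per_s,
    locomotion_scale = locomotion_scale,
    rest_hazard_per_s = rest_hazard_per_s, rest_mean_s = rest_mean_s,
    duration_s = duration_s, fps = fps, n_animals = as.integer(n_animals),
    seed = seed, start_mode = start_mode,
    diffusion_cm_per_sqrt_s = diffusion_cm_per_sqrt_s,
    end_bias_rate_per_s = end_bias_rate_per_s
  ), class = "simulation_config")
}

#' Condition presets for the simulator
#'
#' Parameterizations emulating the assay's reported condition groups:
#' \describe{
#'   \item{naive_male}{T_pref 30.4 C, SD 11.6 C.}
#'   \item{naive_female}{T_pref 32.2 C, SD 13.8 C.}
#'   \item{cfa}{Inflammatory pain: warm-shifted, narrowed preference
#'     (T_pref 36.6 C, SD 6.1 C), reduced locomotion, more resting.}
#'   \item{naive_morphine, cfa_morphine}{Flat preference (no thermal drift)
#'     with hyperlocomotion; CFA+morphine travels farther than
#'     naive+morphine.}
#'   \item{no_gradient}{No thermal drift, mild bias toward the corridor ends:
#'     the qualitative U-shaped room-temperature pattern. Not a validated
#'     quantitative model.}
#' }
#'
#' @param name Preset name.
#' @return A `condition_preset` with fields `name` and `config`.
#' @examples
#' preset("naive_female")$config$t_pref_c # 32.2
#' @export
preset <- function(name) {
  presets <- list(
    naive_male = simulation_config(t_pref_c = 30.4, sd_pref_c = 11.6),
    naive_female = simulation_config(t_pref_c = 32.2, sd_pref_c = 13.8),
    cfa = simulation_config(t_pref_c = 36.6, sd_pref_c = 6.1,
                            locomotion_scale = 0.7,
                            rest_hazard_per_s = 0.1, rest_mean_s = 8),
    naive_morphine = simulation_config(t_pref_c = 31, sd_pref_c = 40,
                                       attraction_rate_per_s = 0,
                                       locomotion_scale = 1.4,
                                       rest_hazard_per_s = 0.01,
                                       rest_mean_s = 3),
    cfa_morphine = simulation_config(t_pref_c = 31, sd_pref_c = 40,
                                     attraction_rate_per_s = 0,
                                     locomotion_scale = 1.8,
                                     rest_hazard_per_s = 0.01,
                                     rest_mean_s = 3),
    no_gradient = simulation_config(t_pref_c = 31, sd_pref_c = 40,
                                    attraction_rate_per_s = 0,
                                    end_bias_rate_per_s = 0.03)
  )
  if (!name %in% names(presets))
    tgt_abort(sprintf("unknown preset '%s'; valid: %s", name,
                      paste(names(presets), collapse = ", ")),
              "tgt_config_error")
  structure(list(name = name, config = presets[[name]]),
            class = "condition_preset")
}

#' Simulate one animal's track
#'
#' Euler-Maruyama integration at the frame rate, with reflection at the
#' corridor ends. The preferred position is `(t_pref - intercept)/slope` and
#' must lie inside the arena. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param arena An [arena_geometry()].
#' @param calibration A [thermal_calibration()].
#' @param animal_id Identifier for the resulting track.
#' @param condition Condition label stored in track metadata.
#' @return An [animal_track()] of `duration_s * fps` frames.
#' @export
simulate_track <- function(config, arena = arena_geometry(),
                           calibration = nominal_calibration(),
                           animal_id = "sim1", condition = NA_character_) {
  slope <- calibration$slope
  L <- arena$length_cm
  x_pref <- (config$t_pref_c - calibration$intercept) / slope
  k <- config$attraction_rate_per_s
  if (k > 0 && (x_pref < 0 || x_pref > L))
    tgt_abort(sprintf("preferred temperature %.1f C maps outside the arena",
                      config$t_pref_c), "tgt_config_error")

  scl <- config$locomotion_scale
  k_eff <- k * scl^2
  sd_x <- config$sd_pref_c / slope
  sigma_w <- if (k > 0) sd_x * sqrt(2 * k) * scl else
    config$diffusion_cm_per_sqrt_s * scl

  fps <- config$fps
  dt <- 1 / fps
  n <- as.integer(round(config$duration_s * fps))
  sqrtdt <- sqrt(dt)

  if (!is.null(config$seed)) set.seed(config$seed)
  x0 <- switch(config$start_mode,
               center = L / 2,
               random = stats::runif(1, 0, L),
               preferred = if (k > 0) x_pref else L / 2)
  noise <- stats::rnorm(n)
  u <- stats::runif(n)

  h <- config$rest_hazard_per_s
  b <- config$end_bias_rate_per_s
  two_sd2 <- 2 * config$sd_pref_c^2
  icept <- calibration$intercept
  tpref <- config$t_pref_c

  x <- numeric(n)
  x[1] <- x0
  rest <- 0L
  for (i in seq_len(n)[-1]) {
    xi <- x[i - 1]
    if (rest > 0L) {
      x[i] <- xi
      rest <- rest - 1L
      next
    }
    drift <- k_eff * (x_pref - xi)
    if (b > 0) drift <- drift + b * ((if (xi > L / 2) L else 0) - xi)
    xi <- xi + drift * dt + sigma_w * sqrtdt * noise[i]
    # reflect into [0, L]; step sizes are small so one or two folds suffice
    while (xi < 0 || xi > L) {
      if (xi < 0) xi <- -xi
      if (xi > L) xi <- 2 * L - xi
    }
    x[i] <- xi
    if (h > 0) {
      w <- exp(-((slope * xi + icept) - tpref)^2 / two_sd2)
      if (u[i] < -expm1(-h * w * dt)) {
        dur <- stats::rexp(1, rate = 1 / config$rest_mean_s)
        rest <- max(1L, as.integer(round(dur * fps)))
      }
    }
  }

  animal_track(data.frame(time_s = (seq_len(n) - 1) * dt, x_cm = x),
               animal_id, fps = fps,
               metadata = list(condition = condition, simulated = TRUE))
}

#' Simulate a cohort of independent animals
#'
#' Per-animal seeds are derived from the top-level seed and the animal index
#' with a counter scheme, so adding or reordering animals never changes any
#' existing animal's path.
#'
#' @param config A [simulation_config()], a [preset()] result, or a preset
#'   name.
#' @param n_animals Number of animals; defaults to `config$n_animals`.
#' @param seed Top-level seed; defaults to `config$seed`.
#' @inheritParams simulate_track
#' @return A [tgt_cohort()] whose track metadata records the condition.
#' @export
simulate_cohort <- function(config, n_animals = NULL, seed = NULL,
                            arena = arena_geometry(),
                            calibration = nominal_calibration()) {
  condition <- NA_character_
  if (is.character(config)) config <- preset(config)
  if (inherits(config, "condition_preset")) {
    condition <- config$name
    config <- config$config
  }
  n_animals <- n_animals %||% config$n_animals
  seed <- seed %||% config$seed
  if (!is_count(n_animals))
    tgt_abort("`n_animals` must be a positive integer", "tgt_config_error")
  tracks <- lapply(seq_len(n_animals), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(seed, i)
    simulate_track(cfg_i, arena, calibration,
                   animal_id = sprintf("sim%03d", i), condition = condition)
  })
  tgt_cohort(tracks, arena, calibration)
}
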