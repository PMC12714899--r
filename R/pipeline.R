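#' Default run configuration
#'
#' The resolved configuration is serializable to YAML and is written next to
#' every run's outputs so any analysis can be reproduced from
#' (inputs, config, seed).
#'
#' @return A nested list with `arena`, `calibration`, `preprocess`, `fit`,
#'   `activity` and `seed` blocks.
#' @export
default_run_config <- function() {
  list(
    arena = list(length_cm = 137, width_cm = 10, n_zones = 14),
    calibration = list(mode = "nominal", points = NULL),
    preprocess = list(exclude_initial_s = 30, analysis_window_s = 600,
                      smoothing_window_frames = 0),
    fit = list(amplitude_mode = "free_3p"),
    activity = list(speed_threshold_cm_s = 0.5, min_bout_s = 3,
                    smoothing_window_frames = 5),
    seed = 1
  )
}

#' Read a run configuration from YAML
#'
#' Keys omitted from the file keep their defaults. Recognized keys follow
#' [default_run_config()]; `calibration.mode` may be `"nominal"` or
#' `"fitted"`, the latter requiring `calibration.points` as a list of
#' `[x_cm, temp_c]` pairs.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      tgt_abort(sprintf("config file not found: %s", path), "tgt_io_error")
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

resolve_arena <- function(config) {
  arena_geometry(config$arena$length_cm, config$arena$width_cm,
                 config$arena$n_zones)
}

resolve_calibration <- function(config, arena) {
  if (identical(config$calibration$mode, "fitted")) {
    pts <- config$calibration$points
    if (is.null(pts))
      tgt_abort("calibration.mode is 'fitted' but no points given",
                "tgt_config_error")
    df <- do.call(rbind, lapply(pts, function(p)
      data.frame(x_cm = p[[1]], temp_c = p[[2]])))
    fit_calibration(df, arena)
  } else {
    nominal_calibration(arena = arena)
  }
}

write_resolved_config <- function(config, out_dir) {
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
}

write_run_log <- function(out_dir, lines) {
  header <- c(sprintf("tgtkit %s",
                      as.character(utils::packageVersion("tgtkit"))),
              format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  writeLines(c(header, lines), file.path(out_dir, "run_log.txt"))
}

#' Simulate a cohort and write it to disk
#'
#' Writes the trajectory CSV (`tracks.csv`, same dialect [read_tracks()]
#' reads), the metadata sidecar, the resolved configuration and a run log.
#'
#' @param preset_name A [preset()] name, or NULL when `config` is given.
#' @param config A [simulation_config()] overriding the preset.
#' @param n_animals,duration_s,seed Override the corresponding config fields.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the simulated [tgt_cohort()].
#' @export
run_simulate <- function(preset_name = NULL, config = NULL, n_animals = NULL,
                         duration_s = NULL, seed = NULL, out_dir) {
  if (is.null(config)) {
    if (is.null(preset_name))
      tgt_abort("give a preset name or a simulation config", "tgt_config_error")
    config <- preset(preset_name)$config
  }
  if (!is.null(duration_s)) config$duration_s <- duration_s
  if (!is.null(n_animals)) config$n_animals <- as.integer(n_animals)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(if (is.null(preset_name)) config else
    structure(list(name = preset_name, config = config),
              class = "condition_preset"))
  write_tracks(cohort, file.path(out_dir, "tracks.csv"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  write_run_log(out_dir, c(
    sprintf("simulate: preset=%s n=%d duration=%gs seed=%s",
            preset_name %||% "(custom)", config$n_animals, config$duration_s,
            format(config$seed))))
  invisible(cohort)
}

#' Analyze a cohort of trajectories end to end
#'
#' Runs preprocess, zone occupancy, pooled Gaussian preference fits (one per
#' condition label) and activity metrics, and writes `occupancy.csv`,
#' `fits.json`, `activity.csv`, `bouts.csv`, the resolved configuration and
#' a run log.
#'
#' @param tracks A tracks CSV path, a list of [animal_track()]s, or a
#'   [tgt_cohort()].
#' @param config A configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @param out_dir Output directory; created if needed. NULL skips writing.
#' @return A list with `profiles`, `fits` (per condition), `activity`,
#'   `arena`, `calibration` — invisibly when `out_dir` is given.
#' @export
run_analyze <- function(tracks, config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  arena <- resolve_arena(config)
  calib <- resolve_calibration(config, arena)
  if (is.character(tracks)) tracks <- read_tracks(tracks, arena = arena)
  if (inherits(tracks, "tgt_cohort")) tracks <- tracks$tracks

  spec <- preprocess_spec(config$preprocess$exclude_initial_s,
                          config$preprocess$analysis_window_s,
                          config$preprocess$smoothing_window_frames)
  pre <- lapply(tracks, preprocess, spec = spec)

  profiles <- lapply(pre, occupancy_profile, arena = arena,
                     calibration = calib)
  conditions <- vapply(profiles, function(p)
    if (is.na(p$condition)) "all" else as.character(p$condition), "")
  fits <- lapply(split(profiles, conditions), function(group)
    fit_preference(occupancy_points(group), config$fit$amplitude_mode))

  activity <- lapply(pre, function(tr)
    resting_summary(tr, arena = arena,
                    speed_threshold_cm_s = config$activity$speed_threshold_cm_s,
                    min_bout_s = config$activity$min_bout_s,
                    smoothing_window_frames = config$activity$smoothing_window_frames))

  result <- list(profiles = profiles, fits = fits, activity = activity,
                 arena = arena, calibration = calib, config = config)
  if (is.null(out_dir)) return(result)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  occ <- do.call(rbind, lapply(profiles, function(p)
    data.frame(animal_id = p$animal_id,
               zone = seq_along(p$percent_by_zone),
               zone_center_temp_c = p$zone_center_temps_c,
               percent_time = p$percent_by_zone,
               window_start_s = p$window[1], window_end_s = p$window[2],
               condition = p$condition)))
  utils::write.csv(occ, file.path(out_dir, "occupancy.csv"), row.names = FALSE)

  jsonlite::write_json(
    lapply(names(fits), function(cn) fit_report(fits[[cn]], cn)),
    file.path(out_dir, "fits.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)

  act <- do.call(rbind, lapply(activity, function(a)
    data.frame(animal_id = a$animal_id, distance_m = a$distance_m,
               resting_percent = a$resting_percent, n_bouts = a$n_bouts,
               mean_bout_s = a$mean_bout_s)))
  utils::write.csv(act, file.path(out_dir, "activity.csv"), row.names = FALSE)
  bouts <- do.call(rbind, lapply(activity, function(a)
    if (nrow(a$bouts))
      cbind(data.frame(animal_id = a$animal_id), a$bouts) else NULL))
  if (is.null(bouts))
    bouts <- data.frame(animal_id = character(0), start_s = numeric(0),
                        duration_s = numeric(0), zone = integer(0),
                        n_frames = integer(0))
  utils::write.csv(bouts, file.path(out_dir, "bouts.csv"), row.names = FALSE)
  write_resolved_config(config, out_dir)
  write_run_log(out_dir, sprintf("analyze: %d animals, %d condition group(s)",
                                 length(profiles), length(fits)))
  invisible(result)
}

#' Compare two analyzed groups
#'
#' Nested extra sum-of-squares F test on the chosen preference parameter,
#' plus t tests on distance traveled and resting percentage when activity
#' tables are supplied.
#'
#' @param occ_a,occ_b Occupancy tables: `occupancy.csv` paths written by
#'   [run_analyze()], data frames with `zone_center_temp_c`/`percent_time`
#'   (or `temp_c`/`percent`), or lists of occupancy profiles.
#' @param parameter `"t_peak"` or `"sd"`.
#' @param activity_a,activity_b Optional activity tables (`activity.csv`
#'   paths or data frames with `distance_m` and `resting_percent`).
#' @param paired Use paired t tests for the activity comparisons.
#' @param amplitude_mode Passed to the preference fits.
#' @param out Optional path for the comparison JSON report.
#' @return A list with the `nested_fit_comparison` (`preference`) and, when
#'   activity data were given, `distance_test` and `resting_test`.
#' @export
run_compare <- function(occ_a, occ_b, parameter = c("t_peak", "sd"),
                        activity_a = NULL, activity_b = NULL, paired = FALSE,
                        amplitude_mode = "free_3p", out = NULL) {
  parameter <- match.arg(parameter)
  load_points <- function(x) {
    if (is.character(x)) x <- utils::read.csv(x)
    if (is.data.frame(x)) {
      if ("zone_center_temp_c" %in% names(x))
        data.frame(temp_c = x$zone_center_temp_c, percent = x$percent_time)
      else x
    } else x
  }
  cmp <- compare_preference(load_points(occ_a), load_points(occ_b),
                            parameter, amplitude_mode)
  result <- list(preference = cmp)

  load_activity <- function(x) if (is.character(x)) utils::read.csv(x) else x
  if (!is.null(activity_a) && !is.null(activity_b)) {
    aa <- load_activity(activity_a)
    ab <- load_activity(activity_b)
    ttest <- if (paired) paired_t_test else welch_t_test
    result$distance_test <- ttest(aa$distance_m, ab$distance_m)
    result$resting_test <- tryCatch(ttest(aa$resting_percent, ab$resting_percent),
                                    tgt_undefined_test_error = function(e) NULL)
  }
  if (!is.null(out)) {
    report <- list(
      parameter_tested = parameter,
      f_stat = cmp$f_stat, df_num = cmp$df_numerator,
      df_den = cmp$df_denominator, p_value = signif(cmp$p_value, 4),
      group_fits = list(fit_report(cmp$fit_a, "group_a"),
                        fit_report(cmp$fit_b, "group_b")))
    for (nm in c("distance_test", "resting_test"))
      if (!is.null(result[[nm]]))
        report[[nm]] <- unclass(result[[nm]])
    jsonlite::write_json(report, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  result
}

#' Effect size and per-group sample size in one call
#'
#' @param delta_mu Detectable mean difference (e.g. degrees C of T_peak).
#' @param sigma Pooled within-group SD in the same units.
#' @param alpha,power,method Passed to [sample_size_per_group()].
#' @return A list with the `effect_size` and `n_per_group`.
#' @examples
#' run_power(1.5, 1.2)$n_per_group # 11
#' @export
run_power <- function(delta_mu, sigma, alpha = 0.05, power = 0.80,
                      method = "normal_approx") {
  if (!is_number(delta_mu) || delta_mu == 0)
    tgt_abort("`delta_mu` must be nonzero", "tgt_config_error")
  if (!is_number(sigma) || sigma <= 0)
    tgt_abort("`sigma` must be positive", "tgt_config_error")
  es <- structure(list(delta_mu = delta_mu, pooled_sigma = sigma,
                       d = delta_mu / sigma), class = "effect_size")
  list(effect_size = es,
       n_per_group = sample_size_per_group(es$d, alpha, power, method))
}
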