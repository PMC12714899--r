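#' Zone-occupancy profile of a track
#'
#' Percent of analyzed frames spent in each zone, indexed by the zone-center
#' temperature. Frame counts (not continuous dwell times) are used, matching
#' the native output of a fixed-rate tracker. Time windows are half-open
#' `[start, end)`.
#'
#' @param track A preprocessed [animal_track()].
#' @param arena An [arena_geometry()].
#' @param calibration A [thermal_calibration()].
#' @param window Numeric `c(start_s, end_s)`; defaults to the full track.
#' @return An `occupancy_profile` with `percent_by_zone` (sums to 100),
#'   `zone_center_temps_c`, `window`, `n_frames` and `animal_id`.
#' @export
occupancy_profile <- function(track, arena = arena_geometry(),
                              calibration = nominal_calibration(),
                              window = NULL) {
  s <- track$samples
  if (is.null(window)) window <- c(0, track_duration(track))
  keep <- s$time_s >= window[1] & s$time_s < window[2]
  n <- sum(keep)
  if (n == 0)
    tgt_abort("no frames inside the requested window", "tgt_empty_window_error")
  z <- zone_of_position(s$x_cm[keep], arena)
  counts <- tabulate(z, nbins = arena$n_zones)
  structure(list(
    animal_id = track$animal_id,
    percent_by_zone = 100 * counts / n,
    zone_center_temps_c = zone_center_temps(arena, calibration),
    window = window, n_frames = n,
    condition = track$metadata$condition %||% NA_character_
  ), class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("Occupancy %s [%g, %g) s, %d frames; peak zone %d (%.1f C, %.1f%%)\n",
              x$animal_id, x$window[1], x$window[2], x$n_frames,
              which.max(x$percent_by_zone),
              x$zone_center_temps_c[which.max(x$percent_by_zone)],
              max(x$percent_by_zone)))
  invisible(x)
}

#' Group mean and SEM of occupancy profiles
#'
#' @param profiles List of [occupancy_profile()] objects sharing the same
#'   zone structure.
#' @param condition Condition label for the group.
#' @return A `group_occupancy` with `mean_percent_by_zone`,
#'   `sem_percent_by_zone` (sample SD / sqrt(n); 0 with a warning for a
#'   single animal), `n_animals` and `zone_center_temps_c`.
#' @export
group_occupancy <- function(profiles, condition = NA_character_) {
  if (!length(profiles))
    tgt_abort("need at least one profile", "tgt_validation_error")
  nz <- vapply(profiles, function(p) length(p$percent_by_zone), 1L)
  if (length(unique(nz)) != 1L)
    tgt_abort("profiles have mixed zone counts", "tgt_mismatch_error")
  mat <- do.call(rbind, lapply(profiles, `[[`, "percent_by_zone"))
  n <- nrow(mat)
  sem <- if (n == 1L) {
    warning("single-animal group: SEM reported as 0", call. = FALSE)
    rep(0, ncol(mat))
  } else {
    apply(mat, 2, stats::sd) / sqrt(n)
  }
  structure(list(condition = condition,
                 mean_percent_by_zone = colMeans(mat),
                 sem_percent_by_zone = sem, n_animals = n,
                 zone_center_temps_c = profiles[[1]]$zone_center_temps_c),
            class = "group_occupancy")
}

#' Occupancy profiles over sliding time windows
#'
#' Profiles for windows `[0, W), [step, step + W), ...`; only windows fully
#' inside the track are produced. Used to compare short- versus long-duration
#' estimates of the preference parameters.
#'
#' @inheritParams occupancy_profile
#' @param window_length_s Window length W in seconds.
#' @param step_s Step between window starts; `step_s = window_length_s`
#'   gives disjoint windows.
#' @return List of `occupancy_profile` objects.
#' @export
sliding_window_occupancy <- function(track, arena = arena_geometry(),
                                     calibration = nominal_calibration(),
                                     window_length_s, step_s) {
  dur <- track_duration(track)
  if (window_length_s > dur + 1e-9)
    tgt_abort("window longer than the track", "tgt_empty_window_error")
  starts <- seq(0, dur - window_length_s + 1e-9, by = step_s)
  lapply(starts, function(s0)
    occupancy_profile(track, arena, calibration,
                      window = c(s0, s0 + window_length_s)))
}

#' Pool occupancy profiles into fit points
#'
#' One `(zone-center temperature, percent)` point per animal and zone — the
#' point set the preference model is fitted to.
#'
#' @param profiles List of [occupancy_profile()] objects.
#' @return Data frame with columns `animal_id`, `zone`, `temp_c`, `percent`.
#' @export
occupancy_points <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(animal_id = p$animal_id,
               zone = seq_along(p$percent_by_zone),
               temp_c = p$zone_center_temps_c,
               percent = p$percent_by_zone)))
}

#' Occupancy of a whole cohort
#'
#' Convenience wrapper: preprocesses every track and returns its occupancy
#' profile over the analysis window.
#'
#' @param cohort A [tgt_cohort()].
#' @param spec A [preprocess_spec()].
#' @return List of `occupancy_profile` objects, one per animal.
#' @export
cohort_occupancy <- function(cohort, spec = preprocess_spec()) {
  lapply(cohort$tracks, function(tr)
    occupancy_profile(preprocess(tr, spec), cohort$arena, cohort$calibration))
}
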