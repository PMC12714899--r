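#' Distance traveled within a time window
#'
#' Sum of frame-to-frame displacements (Euclidean if a transverse `y_cm`
#' column is present, otherwise along the gradient axis only), converted to
#' meters. Positions are median-smoothed first by default: sub-cm tracking
#' jitter is harmless for zone binning but accumulates into spurious path
#' length.
#'
#' @param track A preprocessed [animal_track()].
#' @param window Numeric `c(start_s, end_s)`, half-open; defaults to the full
#'   track.
#' @param smoothing_window_frames Odd running-median window; 0 disables.
#' @return Distance in meters.
#' @export
distance_traveled <- function(track, window = NULL,
                              smoothing_window_frames = 5) {
  s <- track$samples
  if (is.null(window)) window <- c(0, track_duration(track))
  s <- s[s$time_s >= window[1] & s$time_s < window[2], , drop = FALSE]
  if (nrow(s) < 2)
    tgt_abort("need >= 2 frames to measure distance", "tgt_empty_window_error")
  x <- smooth_positions(s$x_cm, smoothing_window_frames)
  d2 <- diff(x)^2
  if ("y_cm" %in% names(s) && !anyNA(s$y_cm))
    d2 <- d2 + diff(smooth_positions(s$y_cm, smoothing_window_frames))^2
  sum(sqrt(d2)) / 100
}

smooth_positions <- function(x, window) {
  if (window >= 3 && length(x) > window)
    as.numeric(stats::runmed(x, window, endrule = "median"))
  else x
}

#' Detect immobility (resting) bouts
#'
#' Frames whose speed falls below `speed_threshold_cm_s` are grouped into
#' maximal runs; runs lasting strictly longer than `min_bout_s` become bouts.
#' A single supra-threshold frame inside a run does not split it
#' (`gap_tolerance_frames`, default 1) — a tracking-jitter guard. Each bout
#' is assigned the zone of its mean position.
#'
#' @param track A preprocessed [animal_track()].
#' @param speed_threshold_cm_s Speed below which a frame counts as immobile.
#' @param min_bout_s Minimum duration (strict) for a run to be a bout; the
#'   assay convention is > 3 s.
#' @param arena Arena for the zone assignment.
#' @param smoothing_window_frames Median window applied to positions before
#'   speeds are computed; 0 disables.
#' @param gap_tolerance_frames Supra-threshold frames tolerated inside a run.
#' @return Data frame with columns `start_s`, `duration_s`, `zone`,
#'   `n_frames`; zero rows when there are no bouts.
#' @export
detect_immobility_bouts <- function(track, speed_threshold_cm_s = 0.5,
                                    min_bout_s = 3.0,
                                    arena = arena_geometry(),
                                    smoothing_window_frames = 5,
                                    gap_tolerance_frames = 1) {
  if (speed_threshold_cm_s <= 0)
    tgt_abort("`speed_threshold_cm_s` must be positive", "tgt_config_error")
  s <- track$samples
  empty <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                      zone = integer(0), n_frames = integer(0))
  if (nrow(s) < 2) return(empty)
  x <- smooth_positions(s$x_cm, smoothing_window_frames)
  speed <- c(NA_real_, abs(diff(x)) * track$fps)
  speed[1] <- speed[2]
  still <- speed < speed_threshold_cm_s

  if (gap_tolerance_frames > 0) {
    # close single-frame (or shorter-than-tolerance) breaks between runs
    r <- rle(still)
    gap <- !r$values & r$lengths <= gap_tolerance_frames
    inner <- which(gap)
    inner <- inner[inner > 1 & inner < length(r$values)]
    r$values[inner] <- TRUE
    still <- inverse.rle(r)
  }

  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths / track$fps > min_bout_s)
  if (!length(keep)) return(empty)
  do.call(rbind, lapply(keep, function(j) {
    i0 <- starts[j]
    i1 <- ends[j]
    data.frame(start_s = s$time_s[i0],
               duration_s = r$lengths[j] / track$fps,
               zone = zone_of_position(mean(s$x_cm[i0:i1]), arena),
               n_frames = r$lengths[j])
  }))
}

#' Activity summary for one animal
#'
#' Aggregates distance traveled, the resting percentage (% of frames inside
#' immobility bouts) and its decomposition across zones (each bout's frames
#' are attributed to the bout's zone). Resting concentrated in the preferred
#' zones mirrors the occupancy profile.
#'
#' @param track A preprocessed [animal_track()].
#' @param bouts Bout table from [detect_immobility_bouts()] on the same
#'   track; computed if omitted.
#' @param arena An [arena_geometry()].
#' @param ... Passed to [detect_immobility_bouts()] when `bouts` is missing.
#' @return An `activity_summary` with `animal_id`, `distance_m`,
#'   `resting_percent`, `resting_percent_by_zone` (sums to
#'   `resting_percent`), `n_bouts`, `mean_bout_s` and the `bouts` table.
#' @export
resting_summary <- function(track, bouts = NULL, arena = arena_geometry(), ...) {
  if (is.null(bouts)) bouts <- detect_immobility_bouts(track, arena = arena, ...)
  n <- nrow(track$samples)
  rest_frames <- sum(bouts$n_frames)
  resting_percent <- 100 * rest_frames / n
  by_zone <- numeric(arena$n_zones)
  if (nrow(bouts))
    for (j in seq_len(nrow(bouts)))
      by_zone[bouts$zone[j]] <- by_zone[bouts$zone[j]] +
        100 * bouts$n_frames[j] / n
  structure(list(animal_id = track$animal_id,
                 distance_m = distance_traveled(track),
                 resting_percent = resting_percent,
                 resting_percent_by_zone = by_zone,
                 n_bouts = nrow(bouts),
                 mean_bout_s = if (nrow(bouts)) mean(bouts$duration_s) else 0,
                 bouts = bouts),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("Activity %s: %.2f m traveled, %.1f%% resting in %d bout(s)\n",
              x$animal_id, x$distance_m, x$resting_percent, x$n_bouts))
  invisible(x)
}
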