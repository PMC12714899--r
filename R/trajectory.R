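#' Construct an animal track
#'
#' A track is a time-ordered table of center-of-mass samples for one animal,
#' carrying its frame rate and metadata (condition, sex, group).
#'
#' @param samples Data frame with columns `time_s`, `x_cm` and optionally
#'   `y_cm`; times must be strictly increasing and non-negative.
#' @param animal_id Identifier string.
#' @param fps Nominal camera frame rate (frames per second).
#' @param metadata Named list; recognized keys: `condition`, `sex`, `group`.
#' @return An object of class `animal_track`.
#' @export
animal_track <- function(samples, animal_id, fps = 15, metadata = list()) {
  if (!is.data.frame(samples) || !all(c("time_s", "x_cm") %in% names(samples)))
    tgt_abort("`samples` needs columns time_s and x_cm", "tgt_schema_error")
  if (nrow(samples) > 0) {
    if (any(samples$time_s < 0))
      tgt_abort("sample times must be >= 0", "tgt_validation_error")
    if (is.unsorted(samples$time_s, strictly = TRUE))
      tgt_abort("sample times must be strictly increasing", "tgt_validation_error")
  }
  structure(
    list(animal_id = as.character(animal_id),
         samples = samples[, intersect(c("time_s", "x_cm", "y_cm"),
                                       names(samples)), drop = FALSE],
         fps = fps, metadata = metadata),
    class = "animal_track"
  )
}

#' @export
print.animal_track <- function(x, ...) {
  dur <- if (nrow(x$samples)) diff(range(x$samples$time_s)) else 0
  cat(sprintf("Track %s: %d samples, %.1f s at %g fps%s\n", x$animal_id,
              nrow(x$samples), dur, x$fps,
              if (!is.null(x$metadata$condition))
                paste0(" [", x$metadata$condition, "]") else ""))
  invisible(x)
}

track_duration <- function(track) {
  n <- nrow(track$samples)
  if (n == 0) return(0)
  # duration as frame count over rate: a 600 s recording at 15 fps carries
  # 9000 frames at t = 0 .. 599.93 s
  n / track$fps
}

#' Assemble tracks into a cohort
#'
#' @param tracks List of [animal_track()] objects.
#' @param arena Shared [arena_geometry()].
#' @param calibration Shared [thermal_calibration()].
#' @return An object of class `tgt_cohort`.
#' @export
tgt_cohort <- function(tracks, arena = arena_geometry(),
                       calibration = nominal_calibration()) {
  if (!length(tracks) || !all(vapply(tracks, inherits, TRUE, "animal_track")))
    tgt_abort("`tracks` must be a non-empty list of animal_track objects",
              "tgt_validation_error")
  structure(list(tracks = tracks, arena = arena, calibration = calibration),
            class = "tgt_cohort")
}

#' @export
print.tgt_cohort <- function(x, ...) {
  cat(sprintf("TGT cohort: %d animals\n", length(x$tracks)))
  invisible(x)
}

#' Preprocessing settings for tracks
#'
#' @param exclude_initial_s Seconds dropped from the start of the recording;
#'   the first 30 s are dominated by exploratory behavior and excluded by
#'   default.
#' @param analysis_window_s Duration in seconds retained after the exclusion.
#' @param smoothing_window_frames Odd window for running-median smoothing of
#'   `x`; 0 disables. Off by default here: occupancy binning is robust to
#'   tracking jitter, while distance metrics apply their own smoothing.
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(exclude_initial_s = 30, analysis_window_s = 600,
                            smoothing_window_frames = 0) {
  if (exclude_initial_s < 0)
    tgt_abort("`exclude_initial_s` must be >= 0", "tgt_config_error")
  if (analysis_window_s <= 0)
    tgt_abort("`analysis_window_s` must be > 0", "tgt_config_error")
  if (smoothing_window_frames != 0 &&
      (smoothing_window_frames < 3 || smoothing_window_frames %% 2 != 1))
    tgt_abort("`smoothing_window_frames` must be 0 or an odd integer >= 3",
              "tgt_config_error")
  structure(list(exclude_initial_s = exclude_initial_s,
                 analysis_window_s = analysis_window_s,
                 smoothing_window_frames = as.integer(smoothing_window_frames)),
            class = "preprocess_spec")
}

#' Number of analyzed frames in a recording
#'
#' `(duration_s - exclude_initial_s) * fps`, floored. A standard 10-min
#' recording at 15 fps with the first 30 s excluded yields 8550 frames.
#'
#' @param duration_s Recording duration in seconds.
#' @param fps Frames per second.
#' @param exclude_initial_s Seconds excluded from the start.
#' @return Integer frame count.
#' @export
analyzed_frame_count <- function(duration_s, fps = 15, exclude_initial_s = 30) {
  if (fps <= 0) tgt_abort("`fps` must be positive", "tgt_config_error")
  if (duration_s <= exclude_initial_s)
    tgt_abort("recording no longer than the exclusion window",
              "tgt_empty_analysis_error")
  as.integer(floor((duration_s - exclude_initial_s) * fps))
}

#' Preprocess a track for analysis
#'
#' Drops the initial exclusion period, clips to the analysis window, re-zeroes
#' timestamps to the window start, and optionally median-smooths positions.
#' Irregular timestamps are resampled to the nominal frame grid by
#' nearest-sample interpolation; gaps up to 1 s are forward-filled and longer
#' gaps recorded in the returned track's metadata (`gap_flags`).
#'
#' @param track An [animal_track()].
#' @param spec A [preprocess_spec()].
#' @return A preprocessed `animal_track` whose samples start at `time_s = 0`.
#' @export
preprocess <- function(track, spec = preprocess_spec()) {
  s <- track$samples
  if (nrow(s) == 0 || max(s$time_s) + 1 / track$fps <= spec$exclude_initial_s)
    tgt_abort(sprintf("track %s has no data after the %gs exclusion",
                      track$animal_id, spec$exclude_initial_s),
              "tgt_empty_analysis_error")

  dt <- 1 / track$fps
  spacing <- diff(s$time_s)
  regular <- nrow(s) < 2 || all(abs(spacing - dt) <= 0.1 * dt)
  gap_flags <- character(0)
  if (!regular) {
    # rebuild on the nominal frame grid; nearest sample wins, gaps > 1 s noted
    grid <- seq(min(s$time_s), max(s$time_s), by = dt)
    idx <- findInterval(grid + dt / 2, s$time_s, all.inside = TRUE)
    nearest <- ifelse(abs(s$time_s[idx + 1] - grid) < abs(grid - s$time_s[idx]),
                      idx + 1, idx)
    gap <- abs(s$time_s[nearest] - grid)
    if (any(gap > 1))
      gap_flags <- sprintf("gap > 1 s near t = %.1f s", grid[which(gap > 1)[1]])
    s <- data.frame(time_s = grid, x_cm = s$x_cm[nearest])
  }

  keep <- s$time_s >= spec$exclude_initial_s &
    s$time_s < spec$exclude_initial_s + spec$analysis_window_s
  if (!any(keep))
    tgt_abort("no frames fall inside the analysis window",
              "tgt_empty_analysis_error")
  s <- s[keep, , drop = FALSE]
  s$time_s <- s$time_s - s$time_s[1]

  if (spec$smoothing_window_frames >= 3 && nrow(s) > spec$smoothing_window_frames)
    s$x_cm <- as.numeric(stats::runmed(s$x_cm, spec$smoothing_window_frames,
                                       endrule = "median"))
  md <- track$metadata
  if (length(gap_flags)) md$gap_flags <- gap_flags
  md$preprocessed <- TRUE
  animal_track(s, track$animal_id, fps = track$fps, metadata = md)
}

#' Read trajectory tables from CSV
#'
#' One row per frame; configurable column names. Returns one track per
#' distinct animal id, samples sorted by time. An optional JSON metadata
#' sidecar (written by [write_tracks()]) restores condition/sex/group labels.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping the canonical fields
#'   `animal_id`, `time_s`, `x_cm` (and optional `y_cm`) to the file's column
#'   names.
#' @param arena If supplied, positions are validated against the arena and
#'   offending row numbers reported.
#' @param metadata_path Optional JSON sidecar path; defaults to
#'   `<path minus .csv>_meta.json` when that file exists.
#' @return List of [animal_track()] objects.
#' @export
read_tracks <- function(path,
                        schema = c(animal_id = "animal_id", time_s = "time_s",
                                   x_cm = "x_cm", y_cm = "y_cm"),
                        arena = NULL, metadata_path = NULL) {
  if (!file.exists(path))
    tgt_abort(sprintf("file not found: %s", path), "tgt_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_s", "x_cm")
  missing_cols <- need[!schema[need] %in% names(raw)]
  if (length(missing_cols))
    tgt_abort(sprintf("missing mandatory column(s): %s",
                      paste(schema[missing_cols], collapse = ", ")),
              "tgt_schema_error")
  df <- data.frame(animal_id = as.character(raw[[schema[["animal_id"]]]]),
                   time_s = suppressWarnings(as.numeric(raw[[schema[["time_s"]]]])),
                   x_cm = suppressWarnings(as.numeric(raw[[schema[["x_cm"]]]])))
  if (!is.na(schema["y_cm"]) && schema[["y_cm"]] %in% names(raw))
    df$y_cm <- suppressWarnings(as.numeric(raw[[schema[["y_cm"]]]]))

  bad <- which(!is.finite(df$time_s) | !is.finite(df$x_cm))
  if (length(bad))
    tgt_abort(sprintf("non-numeric coordinate(s) at data row(s): %s",
                      paste(utils::head(bad, 5), collapse = ", ")),
              "tgt_parse_error")
  if (!is.null(arena)) {
    oob <- which(df$x_cm < 0 | df$x_cm > arena$length_cm)
    if (length(oob))
      tgt_abort(sprintf("position outside the arena at data row(s): %s",
                        paste(utils::head(oob, 5), collapse = ", ")),
                "tgt_validation_error")
  }

  meta <- list()
  if (is.null(metadata_path)) {
    cand <- paste0(sub("\\.csv$", "", path), "_meta.json")
    if (file.exists(cand)) metadata_path <- cand
  }
  if (!is.null(metadata_path) && file.exists(metadata_path))
    meta <- jsonlite::read_json(metadata_path)

  ids <- unique(df$animal_id)
  out <- lapply(ids, function(id) {
    d <- df[df$animal_id == id, setdiff(names(df), "animal_id"), drop = FALSE]
    d <- d[order(d$time_s), , drop = FALSE]
    rownames(d) <- NULL
    fps <- if (nrow(d) > 1) round(1 / stats::median(diff(d$time_s)), 6) else 15
    animal_track(d, id, fps = fps,
                 metadata = if (!is.null(meta[[id]])) meta[[id]] else list())
  })
  names(out) <- ids
  out
}

#' Write trajectory tables to CSV
#'
#' Columns `animal_id,time_s,x_cm[,y_cm]`, rows ordered by animal then time.
#' Metadata (condition/sex/group) goes to a JSON sidecar
#' `<path minus .csv>_meta.json`.
#'
#' @param tracks List of [animal_track()] objects (or a `tgt_cohort`).
#' @param path Output CSV path.
#' @param write_metadata Write the JSON sidecar (default TRUE when any track
#'   carries metadata).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, write_metadata = NULL) {
  if (inherits(tracks, "tgt_cohort")) tracks <- tracks$tracks
  has_y <- any(vapply(tracks, function(t) "y_cm" %in% names(t$samples), TRUE))
  rows <- lapply(tracks, function(t) {
    d <- t$samples
    if (has_y && !"y_cm" %in% names(d)) d$y_cm <- NA_real_
    cbind(data.frame(animal_id = rep(t$animal_id, nrow(d))), d)
  })
  cols <- c("animal_id", "time_s", "x_cm", if (has_y) "y_cm")
  tab <- if (length(rows)) do.call(rbind, rows)[, cols, drop = FALSE] else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) tgt_abort(sprintf("cannot write %s", path), "tgt_io_error")

  meta <- lapply(tracks, `[[`, "metadata")
  names(meta) <- vapply(tracks, `[[`, "", "animal_id")
  meta <- Filter(length, meta)
  if (isTRUE(write_metadata) || (is.null(write_metadata) && length(meta)))
    jsonlite::write_json(meta, paste0(sub("\\.csv$", "", path), "_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
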