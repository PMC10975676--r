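#' Single-subject tracking data
#'
#' A track holds the time-ordered centroid positions of one embryo inside
#' a circular arena (one well of a multi-well plate). Coordinates are in
#' millimetres with the origin at the arena centre, matching the metric
#' thresholds used throughout the cleaning and behavior modules. Frames
#' where the tracker lost the subject are kept as explicit rows with `NA`
#' coordinates rather than dropped, so tracking-loss gaps remain
#' measurable for subject exclusion.
#'
#' @param subject_id Subject identifier (string).
#' @param frames Data frame with columns `frame` (0-based integer, strictly
#'   increasing), `time_s`, `x_mm`, `y_mm`, and optionally `status`
#'   (per-frame annotation: `"raw"`, `"corrected"`, `"interpolated"`,
#'   `"ignored"`, or `"lost"`).
#' @param fps Nominal frame rate (frames per second).
#' @param arena_radius Arena radius in mm. The well diameter of the
#'   48-well plates used in this assay type is not standardized here;
#'   11 mm wells (radius 5.5) are the default and the value is always
#'   configurable.
#' @param plate,well Optional plate/well labels carried as metadata.
#' @return A `vmr_track` object.
#' @export
vmr_track <- function(subject_id, frames, fps = 30, arena_radius = 5.5,
                      plate = NA_character_, well = NA_character_) {
  stopifnot(is.data.frame(frames))
  req <- c("frame", "time_s", "x_mm", "y_mm")
  miss <- setdiff(req, names(frames))
  if (length(miss) > 0) {
    stop("track frames missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) {
    stop("fps must be positive", call. = FALSE)
  }
  if (!is.numeric(arena_radius) || arena_radius <= 0) {
    stop("arena_radius must be positive", call. = FALSE)
  }
  if (is.unsorted(frames$frame, strictly = TRUE)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(frames$time_s)) {
    stop("time_s must be non-decreasing", call. = FALSE)
  }
  if (!"status" %in% names(frames)) {
    frames$status <- ifelse(is.na(frames$x_mm) | is.na(frames$y_mm),
                            "lost", "raw")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      plate = plate, well = well,
      fps = fps,
      arena = list(x = 0, y = 0, radius = arena_radius),
      frames = tibble::as_tibble(frames[c(req, "status")])
    ),
    class = "vmr_track"
  )
}

#' @export
print.vmr_track <- function(x, ...) {
  cat(sprintf("<vmr_track> subject %s: %d frames @ %g fps, arena radius %g mm\n",
              x$subject_id, nrow(x$frames), x$fps, x$arena$radius))
  st <- table(x$frames$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(track) nrow(track$frames)

track_xy <- function(track) {
  cbind(track$frames$x_mm, track$frames$y_mm)
}

#' Read tracks from a track CSV file
#'
#' The track CSV dialect has the header
#' `subject_id,plate,well,frame,time_s,x_mm,y_mm` (UTF-8, `.` decimal).
#' One `vmr_track` is built per subject, frames sorted by frame index.
#' Structural violations are rejected, never silently repaired: missing
#' columns raise a format error, duplicate frame indices an integrity
#' error, and rows with unparseable coordinates are reported with their
#' line numbers.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate used to reconstruct times when needed.
#' @param arena_radius Arena radius (mm) attached to each track.
#' @return List of `vmr_track`, named by subject id.
#' @export
read_tracks <- function(path, fps = 30, arena_radius = 5.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "plate", "well", "frame", "time_s", "x_mm", "y_mm")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("track file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("subject_id", "plate", "well")) {
    df[[col]] <- as.character(df[[col]])
  }
  bad <- which(is.na(df$frame) | is.na(df$time_s) | is.na(df$subject_id))
  if (length(bad) > 0) {
    stop("malformed track rows at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  }
  split_df <- split(df, df$subject_id)
  lapply(split_df, function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (anyDuplicated(d$frame)) {
      stop("non-monotone (duplicated) frame index for subject ",
           d$subject_id[1], call. = FALSE)
    }
    vmr_track(d$subject_id[1], d[c("frame", "time_s", "x_mm", "y_mm")],
              fps = fps, arena_radius = arena_radius,
              plate = d$plate[1], well = d$well[1])
  })
}

#' Write tracks to a track CSV file
#'
#' Inverse of [read_tracks()]: `read_tracks(write_tracks(x, p))` is
#' value-identical on the frame data.
#'
#' @param tracks A `vmr_track` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "vmr_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    data.frame(subject_id = tr$subject_id,
               plate = tr$plate, well = tr$well,
               frame = tr$frames$frame, time_s = tr$frames$time_s,
               x_mm = tr$frames$x_mm, y_mm = tr$frames$y_mm,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a treatment design table
#'
#' Design CSV columns:
#' `subject_id,chemical,dose_ppm,plate,well,breed,excluded,exclusion_reason`.
#' `excluded` is logical (dead, severe deformity, or tracking loss noted
#' at collection time); excluded subjects must carry a reason code.
#'
#' @param path Path to the design CSV.
#' @return Tibble, one row per subject.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "chemical", "dose_ppm", "plate", "well", "breed",
           "excluded", "exclusion_reason")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("design file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop("each subject must map to exactly one design row", call. = FALSE)
  }
  df$excluded <- as.logical(df$excluded)
  if (any(df$excluded & (is.na(df$exclusion_reason) |
                           df$exclusion_reason == ""))) {
    stop("excluded subjects must carry an exclusion_reason", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' The fourteen behavioral endpoint names
#'
#' Ten whole-assay endpoints plus four startle-specific endpoints, in the
#' fixed column order used by [write_endpoints()].
#' @return Character vector of length 14.
#' @export
endpoint_names <- function() {
  c("total_distance_mm", "total_time_swimming_s",
    "mean_step_length_mm", "step_length_sd_mm",
    "mean_turn_angle_rad", "turn_angle_sd_rad",
    "bouts_per_s", "mean_bout_duration_s",
    "mean_bout_speed_mm_s", "mean_bout_turn_angle_rad",
    "startle_magnitude_mm_s", "startle_response_time_s",
    "startle_distance_mm", "distance_after_startle_mm")
}

#' Read / write a per-subject endpoint table
#'
#' One row per subject with a `subject_id` column, all 14 endpoint
#' columns (see [endpoint_names()]) and any treatment metadata columns.
#'
#' @param endpoints Data frame of endpoints.
#' @param path File path.
#' @return `read_endpoints()` returns a tibble; `write_endpoints()`
#'   returns `path` invisibly.
#' @export
write_endpoints <- function(endpoints, path) {
  miss <- setdiff(c("subject_id", endpoint_names()), names(endpoints))
  if (length(miss) > 0) {
    stop("endpoint table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(endpoints, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_endpoints
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  miss <- setdiff(c("subject_id", endpoint_names()), names(df))
  if (length(miss) > 0) {
    stop("endpoint table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}
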