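#' Motion classification configuration
#'
#' Thresholds defining swimming and resting. Swimming is movement of at
#' least `swim_speed_mm_s` (equivalently `swim_step_mm` per frame at the
#' nominal frame rate) sustained for more than `min_swim_frames` frames.
#' Resting is movement below `rest_speed_mm_s`, or faster movement that
#' does not outlast `min_swim_frames`. The two definitions leave a
#' sustained 1-6 mm/s regime unclassified; those frames are labelled
#' `drift` (they contribute to distance but not to swim time or bouts).
#'
#' @param fps Frames per second (default 30).
#' @param swim_speed_mm_s Swim speed threshold (default 6 mm/s).
#' @param swim_step_mm Equivalent per-frame step threshold (default
#'   0.2 mm). A warning is issued if `swim_step_mm * fps` disagrees with
#'   `swim_speed_mm_s`.
#' @param min_swim_frames Minimum duration: a swim run must last *longer*
#'   than this many frames (default 5).
#' @param rest_speed_mm_s Rest speed threshold (default 1 mm/s).
#' @param startle_window_s Post-startle window for the startle endpoints
#'   (default 5 s).
#' @return A `motion_config` list.
#' @export
motion_config <- function(fps = 30, swim_speed_mm_s = 6, swim_step_mm = 0.2,
                          min_swim_frames = 5, rest_speed_mm_s = 1,
                          startle_window_s = 5) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (min_swim_frames < 1) stop("min_swim_frames must be >= 1", call. = FALSE)
  if (abs(swim_step_mm * fps - swim_speed_mm_s) > 1e-8) {
    warning("swim_step_mm * fps (", swim_step_mm * fps,
            ") does not equal swim_speed_mm_s (", swim_speed_mm_s, ")",
            call. = FALSE)
  }
  structure(list(fps = fps, swim_speed_mm_s = swim_speed_mm_s,
                 swim_step_mm = swim_step_mm,
                 min_swim_frames = min_swim_frames,
                 rest_speed_mm_s = rest_speed_mm_s,
                 startle_window_s = startle_window_s),
            class = "motion_config")
}

#' Per-frame kinematics of a corrected track
#'
#' Step length of frame *i* is the straight-line distance from frame
#' *i - 1*; speed is step length times the frame rate; the turning angle
#' is the signed angle of [turning_angle()] computed at frame *i*. The
#' first frame has undefined step and speed; the first and last frames
#' have undefined turning angle.
#'
#' @param track A `vmr_track`.
#' @param cfg A [motion_config()].
#' @return Tibble with columns `frame`, `time_s`, `step_mm`,
#'   `speed_mm_s`, `turn_rad`.
#' @export
frame_kinematics <- function(track, cfg = motion_config(fps = track$fps)) {
  xy <- track_xy(track)
  n <- nrow(xy)
  step <- c(NA_real_, sqrt(rowSums((xy[-1, , drop = FALSE] -
                                      xy[-n, , drop = FALSE])^2)))
  turn <- rep(NA_real_, n)
  if (n >= 3L) {
    turn[2:(n - 1)] <- turning_angle(xy[1:(n - 2), , drop = FALSE],
                                     xy[2:(n - 1), , drop = FALSE],
                                     xy[3:n, , drop = FALSE])
  }
  tibble::tibble(frame = track$frames$frame, time_s = track$frames$time_s,
                 step_mm = step, speed_mm_s = step * cfg$fps,
                 turn_rad = turn)
}

label_runs <- function(ind) {
  # run id for TRUE runs of a logical vector, NA elsewhere
  r <- rle(ind)
  id <- rep(NA_integer_, length(ind))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ct <- 0L
  for (k in seq_along(r$values)) {
    if (isTRUE(r$values[k])) {
      ct <- ct + 1L
      id[starts[k]:ends[k]] <- ct
    }
  }
  id
}

#' Classify per-frame motion state
#'
#' Maximal runs of frames at or above the swim speed threshold lasting
#' longer than `min_swim_frames` are `swim`. Frames below the rest speed
#' threshold are `rest`, as are faster frames belonging to
#' above-threshold runs that do not outlast `min_swim_frames`. Remaining
#' frames (the sustained intermediate regime) are `drift`. Frames with
#' undefined speed (track start, lost fixes) are treated as `rest`.
#'
#' @param kin Kinematics tibble from [frame_kinematics()].
#' @param cfg A [motion_config()].
#' @return Factor of states (`rest`, `drift`, `swim`), one per frame.
#' @export
classify_motion <- function(kin, cfg = motion_config()) {
  speed <- kin$speed_mm_s
  n <- length(speed)
  fast <- !is.na(speed) & speed >= cfg$swim_speed_mm_s
  swim <- rep(FALSE, n)
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] > cfg$min_swim_frames) {
      swim[starts[k]:ends[k]] <- TRUE
    }
  }
  state <- rep("rest", n)
  state[swim] <- "swim"
  moving <- !is.na(speed) & speed >= cfg$rest_speed_mm_s & !swim
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] > cfg$min_swim_frames) {
      state[starts[k]:ends[k]] <- "drift"
    }
  }
  factor(state, levels = c("rest", "drift", "swim"))
}

#' Zero out kinematics during rest
#'
#' During resting frames the speed and distance are set to zero before
#' endpoint computation, so tracker jitter while the larva holds station
#' never counts as movement.
#'
#' @param kin Kinematics tibble.
#' @param states State factor from [classify_motion()].
#' @return The kinematics tibble with `step_mm`/`speed_mm_s` zeroed on
#'   rest frames (undefined first-frame values become 0 as well).
#' @export
zero_rest <- function(kin, states) {
  rest <- states == "rest"
  kin$step_mm[rest | is.na(kin$step_mm)] <- 0
  kin$speed_mm_s[rest | is.na(kin$speed_mm_s)] <- 0
  kin
}

#' Segment swimming bouts
#'
#' One bout per maximal `swim` run: the unit of beat-and-glide
#' locomotion, i.e. the movement between two rest periods.
#'
#' @param states State factor from [classify_motion()].
#' @param kin Kinematics tibble (rest-zeroed or raw; only swim frames
#'   are read).
#' @param cfg A [motion_config()].
#' @return Tibble of bouts: `start_frame`, `end_frame` (half-open, in
#'   row offsets), `duration_s`, `path_length_mm`, `mean_speed_mm_s`,
#'   `mean_turn_angle_rad`.
#' @export
segment_bouts <- function(states, kin, cfg = motion_config()) {
  id <- label_runs(states == "swim")
  if (all(is.na(id))) {
    return(tibble::tibble(start_frame = integer(0), end_frame = integer(0),
                          duration_s = numeric(0), path_length_mm = numeric(0),
                          mean_speed_mm_s = numeric(0),
                          mean_turn_angle_rad = numeric(0)))
  }
  idx <- which(!is.na(id))
  sp <- split(idx, id[idx])
  first <- unname(vapply(sp, `[`, integer(1), 1L))
  len <- unname(lengths(sp))
  path <- vapply(sp, function(ii) sum(kin$step_mm[ii], na.rm = TRUE),
                 numeric(1))
  turn <- vapply(sp, function(ii) mean(kin$turn_rad[ii], na.rm = TRUE),
                 numeric(1))
  dur <- len / cfg$fps
  tibble::tibble(start_frame = first - 1L, end_frame = first - 1L + len,
                 duration_s = dur, path_length_mm = unname(path),
                 mean_speed_mm_s = unname(path) / dur,
                 mean_turn_angle_rad = unname(turn))
}

circular_sd <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) < 2L) return(NA_real_)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  rbar <- min(rbar, 1)
  if (rbar == 0) return(NA_real_)
  sqrt(-2 * log(rbar))
}

#' Whole-assay behavioral endpoints
#'
#' The ten general endpoints, averaged over the recorded assay: total
#' distance, total time swimming, step-length mean and variation,
#' turning-angle mean and variation, and four bout summaries (rate,
#' duration, speed, turning angle). Step and turn summaries are taken
#' over moving (non-rest) frames; the turning-angle standard deviation
#' is circular, since angles live on `(-pi, pi]`. With zero bouts, the
#' three bout averages are `NA` and `bouts_per_s` is 0.
#'
#' @param track A `vmr_track`.
#' @param kin Rest-zeroed kinematics (see [zero_rest()]).
#' @param states State factor.
#' @param bouts Bout tibble from [segment_bouts()].
#' @param cfg A [motion_config()].
#' @return One-row tibble with the 10 general endpoint columns.
#' @export
general_endpoints <- function(track, kin, states, bouts,
                              cfg = motion_config()) {
  duration_s <- diff(range(track$frames$time_s))
  moving <- states != "rest" & !is.na(kin$step_mm) & kin$step_mm > 0
  steps <- kin$step_mm[moving]
  turns <- kin$turn_rad[moving]
  nb <- nrow(bouts)
  tibble::tibble(
    total_distance_mm = sum(kin$step_mm, na.rm = TRUE),
    total_time_swimming_s = sum(states == "swim") / cfg$fps,
    mean_step_length_mm = if (length(steps)) mean(steps) else 0,
    step_length_sd_mm = if (length(steps) > 1) stats::sd(steps) else 0,
    mean_turn_angle_rad = mean(turns, na.rm = TRUE),
    turn_angle_sd_rad = circular_sd(turns),
    bouts_per_s = nb / duration_s,
    mean_bout_duration_s = if (nb) mean(bouts$duration_s) else NA_real_,
    mean_bout_speed_mm_s = if (nb) mean(bouts$mean_speed_mm_s) else NA_real_,
    mean_bout_turn_angle_rad = if (nb) {
      mean(bouts$mean_turn_angle_rad, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Startle-response endpoints
#'
#' For each startle (light transition) at time `t_s`, using the
#' rest-zeroed speeds: the maximum speed inside the half-open window
#' `(t_s, t_s + startle_window_s]` is located (ties broken by earliest
#' time, a reaction-time reading); speed "at the startle" is the speed
#' of the frame at or immediately before `t_s`. The four endpoints per
#' startle are the response magnitude (max minus speed at startle),
#' response time (time of max minus `t_s`), startle distance (path from
#' `t_s` to the max-speed frame), and distance after startle (path over
#' the whole window). Each endpoint is the mean over all startles; a
#' startle whose window extends past the recording is truncated and
#' noted.
#'
#' @param track A `vmr_track`.
#' @param kin Rest-zeroed kinematics.
#' @param schedule A `vmr_schedule`.
#' @param cfg A [motion_config()].
#' @return One-row tibble with the 4 startle endpoint columns.
#' @export
startle_endpoints <- function(track, kin, schedule, cfg = motion_config()) {
  ev <- startle_events(schedule)
  if (nrow(ev) == 0L) {
    stop("schedule defines no startle events", call. = FALSE)
  }
  t <- kin$time_s
  t_end <- t[length(t)]
  per <- lapply(ev$time_s, function(ts) {
    if (ts >= t_end) return(NULL)
    if (ts + cfg$startle_window_s > t_end) {
      message("startle at ", ts, " s truncated by end of recording")
    }
    at_idx <- max(which(t <= ts))
    win <- which(t > ts & t <= ts + cfg$startle_window_s)
    if (length(win) == 0L) return(NULL)
    v <- kin$speed_mm_s[win]
    imax <- win[which.max(v)] # which.max takes the earliest tie
    data.frame(
      magnitude = max(v) - kin$speed_mm_s[at_idx],
      response_time = t[imax] - ts,
      startle_distance = sum(kin$step_mm[win[win <= imax]]),
      distance_after = sum(kin$step_mm[win])
    )
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L) {
    stop("no startle event falls within the recorded data", call. = FALSE)
  }
  tibble::tibble(
    startle_magnitude_mm_s = mean(per$magnitude),
    startle_response_time_s = mean(per$response_time),
    startle_distance_mm = mean(per$startle_distance),
    distance_after_startle_mm = mean(per$distance_after)
  )
}

#' Compute all fourteen endpoints for one subject
#'
#' Runs the full per-subject chain: kinematics, motion classification,
#' rest zeroing, bout segmentation, then the ten general and four
#' startle endpoints.
#'
#' @param track A corrected `vmr_track`.
#' @param schedule A `vmr_schedule`.
#' @param cfg A [motion_config()].
#' @return One-row tibble: `subject_id` plus the 14 endpoint columns of
#'   [endpoint_names()].
#' @export
compute_endpoints <- function(track, schedule,
                              cfg = motion_config(fps = track$fps)) {
  kin <- frame_kinematics(track, cfg)
  states <- classify_motion(kin, cfg)
  kin <- zero_rest(kin, states)
  bouts <- segment_bouts(states, kin, cfg)
  gen <- general_endpoints(track, kin, states, bouts, cfg)
  sta <- startle_endpoints(track, kin, schedule, cfg)
  tibble::tibble(subject_id = track$subject_id, gen, sta)
}
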