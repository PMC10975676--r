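#' Cleaning configuration for tracking-artifact detection
#'
#' Thresholds for the two centroid-tracking error detectors and the
#' surrounding rules. Type-1 errors are sub-millimetre jitter events in
#' which the tracked point switches between two parts of the fish body;
#' type-2 errors are single-frame jumps to the arena edge and back. Both
#' present as out-and-back spikes: a sharp turn at the candidate frame
#' combined with previous and future locations that are close together.
#'
#' @param type1_angle_deg Turning-angle threshold at the candidate frame
#'   for type-1 flags (default 150; strict `>`).
#' @param type1_dist_mm Maximum distance between previous and future
#'   locations for type-1 flags (default 0.06; strict `<`).
#' @param type1_ignore_move_mm Movement below this is ignored inside
#'   high-error periods (default 0.2 mm; strict `<`).
#' @param type2_angle_deg Turning-angle threshold for type-2 flags
#'   (default 160; strict `>`).
#' @param type2_net_dist_mm Maximum previous-to-future distance for
#'   type-2 flags (default 0.6; inclusive `<=`).
#' @param type2_leg_min_mm Minimum length of each out-and-back leg
#'   (default 2; inclusive `>=`).
#' @param type2_leg_len_tol Maximum relative difference between the two
#'   leg lengths, computed as `|L1 - L2| / max(L1, L2)` (default 0.30;
#'   inclusive `<=`).
#' @param high_error_window_s Sliding window length defining a
#'   high-error period (default 1 s).
#' @param high_error_min_flags Minimum flagged frames inside a window
#'   for it to count as high-error (default 3).
#' @param lost_fix_max_s Longest tolerated tracking-loss gap before a
#'   subject is excluded (default 2 s, the working reading of "multiple
#'   seconds"; strict `>` excludes).
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(type1_angle_deg = 150, type1_dist_mm = 0.06,
                            type1_ignore_move_mm = 0.2,
                            type2_angle_deg = 160, type2_net_dist_mm = 0.6,
                            type2_leg_min_mm = 2, type2_leg_len_tol = 0.30,
                            high_error_window_s = 1,
                            high_error_min_flags = 3,
                            lost_fix_max_s = 2) {
  cfg <- list(type1_angle_deg = type1_angle_deg,
              type1_dist_mm = type1_dist_mm,
              type1_ignore_move_mm = type1_ignore_move_mm,
              type2_angle_deg = type2_angle_deg,
              type2_net_dist_mm = type2_net_dist_mm,
              type2_leg_min_mm = type2_leg_min_mm,
              type2_leg_len_tol = type2_leg_len_tol,
              high_error_window_s = high_error_window_s,
              high_error_min_flags = high_error_min_flags,
              lost_fix_max_s = lost_fix_max_s)
  num <- unlist(cfg[setdiff(names(cfg), "type2_leg_len_tol")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all cleaning thresholds must be positive", call. = FALSE)
  }
  if (type1_angle_deg > 180 || type2_angle_deg > 180) {
    stop("angle thresholds must lie in (0, 180]", call. = FALSE)
  }
  if (type2_leg_len_tol < 0 || type2_leg_len_tol > 1) {
    stop("type2_leg_len_tol must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cleaning_config")
}

#' Signed turning angle at a position
#'
#' The turning angle at `p_cur` is the difference between the
#' four-quadrant arctangent headings of the two trajectories
#' `p_prev -> p_cur` and `p_cur -> p_next`, wrapped to `(-pi, pi]`. Zero
#' is straight-ahead movement; negative values are right turns and
#' positive values left turns (y axis up). A full reversal maps to the
#' wrap boundary `pi`. If either segment has zero length the angle is
#' undefined and `NA` is returned, leaving the caller to decide.
#'
#' Inputs may be single `c(x, y)` points or two-column matrices of
#' points, in which case the computation is vectorized row-wise.
#'
#' @param p_prev,p_cur,p_next Positions (length-2 vectors or n x 2
#'   matrices).
#' @return Signed angle(s) in radians in `(-pi, pi]`, `NA` where
#'   undefined.
#' @export
#' @examples
#' turning_angle(c(0, 0), c(1, 0), c(2, 0))   # 0, straight ahead
#' turning_angle(c(0, 0), c(1, 0), c(1, -1))  # -pi/2, right turn
#' turning_angle(c(0, 0), c(1, 0), c(0, 0))   # pi, full reversal
turning_angle <- function(p_prev, p_cur, p_next) {
  as_mat <- function(p) {
    if (is.matrix(p)) p else matrix(p, ncol = 2)
  }
  a <- as_mat(p_prev); b <- as_mat(p_cur); c_ <- as_mat(p_next)
  v1 <- b - a
  v2 <- c_ - b
  zero <- (v1[, 1] == 0 & v1[, 2] == 0) | (v2[, 1] == 0 & v2[, 2] == 0)
  ang <- atan2(v2[, 2], v2[, 1]) - atan2(v1[, 2], v1[, 1])
  # wrap to (-pi, pi]
  ang <- ang - 2 * pi * floor((ang + pi) / (2 * pi))
  ang[ang == -pi] <- pi
  ang[zero] <- NA_real_
  if (length(ang) == 1L) ang[[1L]] else ang
}

# per-frame spike geometry shared by both detectors; NA-safe
spike_geometry <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) {
    return(list(angle = numeric(0), net = numeric(0),
                leg1 = numeric(0), leg2 = numeric(0), idx = integer(0)))
  }
  i <- 2:(n - 1)
  prev <- xy[i - 1, , drop = FALSE]
  cur <- xy[i, , drop = FALSE]
  nxt <- xy[i + 1, , drop = FALSE]
  list(
    angle = turning_angle(prev, cur, nxt),
    net = sqrt(rowSums((nxt - prev)^2)),
    leg1 = sqrt(rowSums((cur - prev)^2)),
    leg2 = sqrt(rowSums((nxt - cur)^2)),
    idx = i
  )
}

#' Flag type-1 tracking errors (body-point-switch jitter)
#'
#' Frame *i* is flagged iff the absolute turning angle at *i* exceeds
#' `type1_angle_deg` *and* the distance between the previous and future
#' locations is below `type1_dist_mm`. The first and last frames can
#' never be flagged (no two-sided neighbours), and frames with undefined
#' turning angle (zero-length segment, e.g. a perfectly stationary fish)
#' are never flagged.
#'
#' @param track A `vmr_track` with at least 3 frames (shorter tracks
#'   return an empty flag set).
#' @param cfg A [cleaning_config()].
#' @return Logical vector, one element per frame.
#' @export
flag_type1 <- function(track, cfg = cleaning_config()) {
  xy <- track_xy(track)
  out <- rep(FALSE, nrow(xy))
  g <- spike_geometry(xy)
  if (length(g$idx) == 0L) return(out)
  hit <- !is.na(g$angle) & !is.na(g$net) &
    abs(g$angle) > cfg$type1_angle_deg * pi / 180 &
    g$net < cfg$type1_dist_mm
  out[g$idx[hit]] <- TRUE
  out
}

#' Flag type-2 tracking errors (arena-edge jumps)
#'
#' Frame *i* is flagged iff all four criteria hold: absolute turning
#' angle above `type2_angle_deg`; previous-to-future distance at most
#' `type2_net_dist_mm`; both out-and-back legs at least
#' `type2_leg_min_mm`; and relative leg-length difference
#' `|L1 - L2| / max(L1, L2)` at most `type2_leg_len_tol`.
#'
#' @inheritParams flag_type1
#' @return Logical vector, one element per frame.
#' @export
flag_type2 <- function(track, cfg = cleaning_config()) {
  xy <- track_xy(track)
  out <- rep(FALSE, nrow(xy))
  g <- spike_geometry(xy)
  if (length(g$idx) == 0L) return(out)
  reldiff <- abs(g$leg1 - g$leg2) / pmax(g$leg1, g$leg2)
  hit <- !is.na(g$angle) & !is.na(g$net) &
    abs(g$angle) > cfg$type2_angle_deg * pi / 180 &
    g$net <= cfg$type2_net_dist_mm &
    g$leg1 >= cfg$type2_leg_min_mm & g$leg2 >= cfg$type2_leg_min_mm &
    reldiff <= cfg$type2_leg_len_tol
  out[g$idx[hit]] <- TRUE
  out
}

#' Run both tracking-error detectors
#'
#' Combines [flag_type1()] and [flag_type2()] into a per-frame label
#' vector. The labels are mutually exclusive; when a frame satisfies
#' both detectors the type-2 label (larger displacement class) takes
#' precedence. High-error periods are computed from the flag density: a
#' frame is inside a high-error period if any sliding window of
#' `high_error_window_s` containing it holds at least
#' `high_error_min_flags` flagged frames.
#'
#' @inheritParams flag_type1
#' @return A `vmr_flags` object: list with `labels` (character vector,
#'   `"clean"`, `"type1"` or `"type2"`) and `high_error` (logical
#'   vector).
#' @export
flag_artifacts <- function(track, cfg = cleaning_config()) {
  t1 <- flag_type1(track, cfg)
  t2 <- flag_type2(track, cfg)
  labels <- rep("clean", n_frames(track))
  labels[t1] <- "type1"
  labels[t2] <- "type2" # precedence over type1
  flagged <- labels != "clean"
  w <- max(1L, round(cfg$high_error_window_s * track$fps))
  high <- rep(FALSE, length(labels))
  if (any(flagged) && length(labels) >= w) {
    cs <- cumsum(c(0L, as.integer(flagged)))
    starts <- seq_len(length(labels) - w + 1L)
    counts <- cs[starts + w] - cs[starts]
    qualifying <- which(counts >= cfg$high_error_min_flags)
    for (s in qualifying) high[s:(s + w - 1L)] <- TRUE
  }
  structure(list(labels = labels, high_error = high), class = "vmr_flags")
}

#' @export
print.vmr_flags <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("clean", "type1", "type2")))
  cat(sprintf("<vmr_flags> %d frames: %d type1, %d type2, %d in high-error periods\n",
              length(x$labels), tab[["type1"]], tab[["type2"]],
              sum(x$high_error)))
  invisible(x)
}

flagged_runs <- function(flagged) {
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Replace flagged locations by equidistant interpolation
#'
#' Each maximal run of consecutive flagged frames is replaced by points
#' evenly spaced on the straight segment between the nearest clean
#' (non-error) locations on either side: for a run of *k* frames between
#' anchors A and B, point *j* goes to `A + j * (B - A) / (k + 1)`.
#' Clean frames are bit-identical before and after. Runs touching the
#' track boundary (or bounded by a lost-fix gap) have no two-sided
#' anchors; their frames are labelled `"ignored"` and left in place,
#' with a warning.
#'
#' @param track A `vmr_track`.
#' @param flags A `vmr_flags` from [flag_artifacts()] (or a logical
#'   vector of flagged frames).
#' @return The corrected `vmr_track`, with replaced frames labelled
#'   `"interpolated"` in `status`.
#' @export
correct_flags <- function(track, flags) {
  flagged <- if (inherits(flags, "vmr_flags")) {
    flags$labels != "clean"
  } else {
    as.logical(flags)
  }
  stopifnot(length(flagged) == n_frames(track))
  if (!any(flagged)) return(track)
  fr <- track$frames
  xy <- track_xy(track)
  runs <- flagged_runs(flagged)
  n <- nrow(xy)
  for (r in seq_len(nrow(runs))) {
    a <- runs$start[r] - 1L
    b <- runs$end[r] + 1L
    k <- runs$end[r] - runs$start[r] + 1L
    anchors_ok <- a >= 1L && b <= n &&
      !anyNA(xy[a, ]) && !anyNA(xy[b, ])
    if (!anchors_ok) {
      fr$status[runs$start[r]:runs$end[r]] <- "ignored"
      warning("flagged run at frames ", fr$frame[runs$start[r]], "-",
              fr$frame[runs$end[r]],
              " touches a track boundary; frames marked ignored",
              call. = FALSE)
      next
    }
    j <- seq_len(k)
    fr$x_mm[runs$start[r]:runs$end[r]] <- xy[a, 1] + j * (xy[b, 1] - xy[a, 1]) / (k + 1)
    fr$y_mm[runs$start[r]:runs$end[r]] <- xy[a, 2] + j * (xy[b, 2] - xy[a, 2]) / (k + 1)
    fr$status[runs$start[r]:runs$end[r]] <- "interpolated"
  }
  track$frames <- fr
  track
}

#' Suppress micro-movement inside high-error periods
#'
#' Within high-error periods (see [flag_artifacts()]), inter-frame
#' displacements smaller than `type1_ignore_move_mm` are ignored as
#' movement: the corresponding steps are zeroed and the positions inside
#' the window rebuilt from the retained steps, so sub-threshold jitter
#' contributes nothing to path length. Frames outside high-error periods
#' are unchanged.
#'
#' @param track A `vmr_track` (normally after [correct_flags()]).
#' @param flags The pre-correction `vmr_flags`, which carry the
#'   high-error period markers.
#' @param cfg A [cleaning_config()].
#' @return The `vmr_track` with micro-movement suppressed.
#' @export
suppress_micro_movement <- function(track, flags, cfg = cleaning_config()) {
  stopifnot(inherits(flags, "vmr_flags"))
  high <- flags$high_error
  if (!any(high)) return(track)
  fr <- track$frames
  runs <- flagged_runs(high)
  for (r in seq_len(nrow(runs))) {
    a <- max(runs$start[r], 2L)
    b <- runs$end[r]
    if (b < a) next
    i <- a:b
    dx <- fr$x_mm[i] - fr$x_mm[i - 1L]
    dy <- fr$y_mm[i] - fr$y_mm[i - 1L]
    d <- sqrt(dx^2 + dy^2)
    drop <- !is.na(d) & d < cfg$type1_ignore_move_mm
    dx[drop] <- 0
    dy[drop] <- 0
    dx[is.na(dx)] <- 0
    dy[is.na(dy)] <- 0
    fr$x_mm[i] <- fr$x_mm[a - 1L] + cumsum(dx)
    fr$y_mm[i] <- fr$y_mm[a - 1L] + cumsum(dy)
  }
  track$frames <- fr
  track
}

longest_gap_s <- function(track) {
  lost <- is.na(track$frames$x_mm) | is.na(track$frames$y_mm)
  if (!any(lost)) return(0)
  r <- rle(lost)
  max(r$lengths[r$values]) / track$fps
}

#' Exclude subjects unfit for behavioral analysis
#'
#' Removes (a) subjects flagged in the design as dead or severely
#' deformed (any design-level `excluded` flag) and (b) subjects whose
#' longest tracking-loss gap exceeds `lost_fix_max_s`.
#'
#' @param tracks List of `vmr_track`.
#' @param design Design tibble from [read_design()] (or `NULL` to apply
#'   only the tracking-loss rule).
#' @param cfg A [cleaning_config()].
#' @return List with `kept` (the retained tracks) and `report` (tibble
#'   `subject_id`, `reason` for every exclusion).
#' @export
exclude_subjects <- function(tracks, design = NULL, cfg = cleaning_config()) {
  ids <- vapply(tracks, function(tr) tr$subject_id, character(1))
  reason <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(design)) {
    ex <- design[design$excluded, , drop = FALSE]
    hit <- ids %in% ex$subject_id
    reason[hit] <- ex$exclusion_reason[match(ids[hit], ex$subject_id)]
  }
  for (k in seq_along(tracks)) {
    if (!is.na(reason[k])) next
    if (longest_gap_s(tracks[[k]]) > cfg$lost_fix_max_s) {
      reason[k] <- "tracking-loss"
    }
  }
  keep <- is.na(reason)
  list(
    kept = tracks[keep],
    report = tibble::tibble(subject_id = ids[!keep],
                            reason = unname(reason[!keep]))
  )
}

#' Clean a track end to end
#'
#' Convenience wrapper: detect both artifact types, interpolate flagged
#' runs, then suppress micro-movement inside high-error periods.
#'
#' @inheritParams flag_type1
#' @return List with `track` (cleaned), `flags` (the pre-correction
#'   `vmr_flags`).
#' @export
clean_track <- function(track, cfg = cleaning_config()) {
  flags <- flag_artifacts(track, cfg)
  out <- correct_flags(track, flags)
  out <- suppress_micro_movement(out, flags, cfg)
  list(track = out, flags = flags)
}
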