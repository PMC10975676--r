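#' Construct a light/dark schedule
#'
#' A light schedule is an ordered, contiguous sequence of illumination
#' intervals. Abrupt transitions between light states are the visual
#' startle stimuli of the VMR assay, so the schedule fully determines the
#' startle-event times. The state the arena was in *before* recording
#' started (typically the dark acclimation period, during which no track
#' data are collected) is kept as an attribute so that the onset of the
#' first interval counts as a startle when the state changes at time zero.
#'
#' @param states Character vector of interval states, each `"light"` or
#'   `"dark"`.
#' @param durations_s Numeric vector of interval durations in seconds
#'   (recycled against `states` if length one).
#' @param pre_state State before the first interval (`"dark"` for the
#'   standard dark-acclimated assay, or `NA` to suppress the onset event).
#' @return A `vmr_schedule`: a tibble with columns `state`, `start_s`,
#'   `end_s` and a `pre_state` attribute.
#' @seealso [vmr_schedule()] for the standard 4-cycle assay,
#'   [startle_events()] for the derived stimulus times.
#' @export
#' @examples
#' light_schedule(c("light", "dark"), 180)
light_schedule <- function(states, durations_s, pre_state = "dark") {
  states <- as.character(states)
  if (length(states) == 0L) {
    stop("schedule must contain at least one interval", call. = FALSE)
  }
  if (!all(states %in% c("light", "dark"))) {
    stop("schedule states must be 'light' or 'dark'", call. = FALSE)
  }
  durations_s <- rep_len(as.numeric(durations_s), length(states))
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("interval durations must be positive and finite", call. = FALSE)
  }
  if (!is.na(pre_state) && !pre_state %in% c("light", "dark")) {
    stop("pre_state must be 'light', 'dark' or NA", call. = FALSE)
  }
  end_s <- cumsum(durations_s)
  out <- tibble::tibble(
    state = states,
    start_s = c(0, end_s[-length(end_s)]),
    end_s = end_s
  )
  structure(out, pre_state = pre_state,
            class = c("vmr_schedule", class(out)))
}

#' Standard VMR assay schedule
#'
#' The default visual-motor-response protocol: after a 10 min dark
#' acclimation (not recorded), embryos experience four cycles of
#' alternating 3 min light and 3 min dark periods, i.e. eight 180 s
#' intervals (24 min of recorded data) delivering eight startles: four
#' dark-to-light (including the onset at time zero) and four
#' light-to-dark.
#'
#' @param cycles Number of light/dark cycles (default 4).
#' @param period_s Duration of each light or dark interval in seconds
#'   (default 180).
#' @param first_state State of the first recorded interval (default
#'   `"light"`, following the dark acclimation).
#' @return A `vmr_schedule`.
#' @export
#' @examples
#' sched <- vmr_schedule()
#' schedule_duration(sched) / 60 # 24 minutes of recorded data
#' nrow(startle_events(sched))   # 8 startles
vmr_schedule <- function(cycles = 4, period_s = 180, first_state = "light") {
  second <- if (first_state == "light") "dark" else "light"
  light_schedule(rep(c(first_state, second), cycles), period_s,
                 pre_state = second)
}

#' Total recorded duration of a schedule, in seconds
#' @param schedule A `vmr_schedule`.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "vmr_schedule"))
  schedule$end_s[nrow(schedule)]
}

#' Startle events of a light schedule
#'
#' Every change of illumination state is a startle. Internal interval
#' boundaries always qualify; the start of recording additionally
#' qualifies when the pre-recording state (acclimation) differs from the
#' first interval's state.
#'
#' @param schedule A `vmr_schedule`.
#' @return Tibble with columns `time_s` and `direction`
#'   (`"dark_to_light"` or `"light_to_dark"`).
#' @export
startle_events <- function(schedule) {
  stopifnot(inherits(schedule, "vmr_schedule"))
  pre <- attr(schedule, "pre_state")
  from <- c(pre, schedule$state[-nrow(schedule)])
  to <- schedule$state
  at <- schedule$start_s
  keep <- !is.na(from) & from != to
  tibble::tibble(
    time_s = at[keep],
    direction = ifelse(to[keep] == "light", "dark_to_light", "light_to_dark")
  )
}

#' Read / write a schedule configuration file
#'
#' The on-disk format is a plain CSV of ordered `state,duration_s`
#' records, optionally preceded by a `# pre_state: <state>` comment line.
#' Files carrying explicit `start_s`/`end_s` columns are validated for
#' contiguity and rejected if intervals overlap or leave gaps.
#'
#' @param path File path.
#' @return `read_schedule()` returns a `vmr_schedule`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  header <- readLines(path, n = 5L)
  pre <- "dark"
  m <- grep("^#\\s*pre_state:", header, value = TRUE)
  if (length(m) > 0) {
    pre <- trimws(sub("^#\\s*pre_state:", "", m[1]))
    if (pre == "NA") pre <- NA_character_
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"state" %in% names(df)) {
    stop("schedule file must have a 'state' column", call. = FALSE)
  }
  if (all(c("start_s", "end_s") %in% names(df))) {
    df <- df[order(df$start_s), , drop = FALSE]
    if (any(df$end_s <= df$start_s)) {
      stop("schedule intervals must have end_s > start_s", call. = FALSE)
    }
    gaps <- df$start_s[-1] - df$end_s[-nrow(df)]
    if (any(abs(gaps) > 1e-9)) {
      stop("schedule intervals must be contiguous and non-overlapping",
           call. = FALSE)
    }
    return(light_schedule(df$state, df$end_s - df$start_s, pre_state = pre))
  }
  if (!"duration_s" %in% names(df)) {
    stop("schedule file must have 'duration_s' or 'start_s'/'end_s' columns",
         call. = FALSE)
  }
  light_schedule(df$state, df$duration_s, pre_state = pre)
}

#' @rdname read_schedule
#' @param schedule A `vmr_schedule` to write.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "vmr_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pre_state: %s", attr(schedule, "pre_state")), con)
  utils::write.csv(
    data.frame(state = schedule$state,
               duration_s = schedule$end_s - schedule$start_s),
    con, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
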