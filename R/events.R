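# Step segmentation, limb-role assignment, and time normalization.
#
# A step runs from one toe-off to the next toe-off of the contralateral leg,
# beginning with front-foot block clearance (TO_0). Flight time is toe-off to
# the contralateral touchdown; contact time is touchdown to the same-side
# toe-off closing the step.

#' Assign leading/trailing limb roles for a step
#'
#' The swing leg at the toe-off opening a step is "leading" and the stance
#' (toe-off) leg "trailing" for the duration of that step; roles alternate
#' every step. For step 1 the opening toe-off is front-block clearance, so the
#' rear-block leg leads.
#'
#' @param step_index 1-based step number.
#' @param front_block_side `"left"` or `"right"`.
#' @return named list with `leading` and `trailing` sides.
#' @export
assign_limb_roles <- function(step_index, front_block_side) {
  front_block_side <- match.arg(front_block_side, c("left", "right"))
  stopifnot(step_index >= 1)
  other <- function(s) if (s == "left") "right" else "left"
  if (step_index %% 2 == 1)
    list(leading = other(front_block_side), trailing = front_block_side)
  else
    list(leading = front_block_side, trailing = other(front_block_side))
}

#' Segment a trial into step windows
#'
#' Step k spans toe-off k-1 (block clearance `TO_0` for k = 1) to the next,
#' contralateral, toe-off, and must contain exactly one touchdown (of the
#' leading leg).
#'
#' @param trial a [sprint_trial()].
#' @param n_steps number of steps to extract; `NULL` takes all available.
#' @return a `data.frame` of class `step_windows` with columns `step_index`,
#'   `t_start`, `t_td`, `t_end`, `leading_side`, `trailing_side`,
#'   `flight_time`, `contact_time`, `touchdown_pct`.
#' @export
segment_steps <- function(trial, n_steps = NULL) {
  stopifnot(inherits(trial, "sprint_trial"))
  ev <- trial$events
  to <- ev[ev$kind == "toe_off", , drop = FALSE]
  td <- ev[ev$kind == "touchdown", , drop = FALSE]
  i0 <- which(to$label == "TO_0")
  if (length(i0) != 1L)
    stop("segment_steps: trial must contain exactly one TO_0 event",
         call. = FALSE)
  to <- to[seq(i0, nrow(to)), , drop = FALSE]
  avail <- nrow(to) - 1L
  if (is.null(n_steps)) n_steps <- avail
  if (avail < n_steps)
    stop(sprintf("segment_steps: %d steps requested but only %d toe-offs after TO_0",
                 n_steps, avail), call. = FALSE)
  if (to$side[1] != trial$front_block_side)
    stop("segment_steps: TO_0 side disagrees with front_block_side",
         call. = FALSE)
  steps <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    t_start <- to$time_s[k]
    t_end <- to$time_s[k + 1L]
    if (to$side[k + 1L] == to$side[k])
      stop(sprintf("segment_steps: step %d is not closed by a contralateral toe-off", k),
           call. = FALSE)
    roles <- assign_limb_roles(k, trial$front_block_side)
    inside <- td$time_s > t_start & td$time_s < t_end
    if (sum(inside) != 1L)
      stop(sprintf("segment_steps: step %d contains %d touchdowns (expected 1)",
                   k, sum(inside)), call. = FALSE)
    t_td <- td$time_s[inside]
    if (td$side[inside] != roles$leading)
      stop(sprintf("segment_steps: step %d touchdown side is not the leading leg", k),
           call. = FALSE)
    steps[[k]] <- data.frame(
      step_index = k, t_start = t_start, t_td = t_td, t_end = t_end,
      leading_side = roles$leading, trailing_side = roles$trailing,
      flight_time = t_td - t_start, contact_time = t_end - t_td,
      touchdown_pct = 100 * (t_td - t_start) / (t_end - t_start),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, steps)
  class(out) <- c("step_windows", "data.frame")
  out
}

#' Time-normalize an angle series over a step window
#'
#' Linear interpolation of the angle signal at `n` equally spaced times
#' spanning `[t_start, t_end]` inclusive.
#'
#' @param series an [angle_series()].
#' @param window one row of [segment_steps()] output (or any list with
#'   `t_start` and `t_end`).
#' @param n number of output points (default 101).
#' @return numeric vector of `n` interpolated angles.
#' @export
time_normalize <- function(series, window, n = 101L) {
  stopifnot(inherits(series, "angle_series"), n >= 3)
  sp <- series_span(series)
  if (window$t_start < sp[1] - 1e-9 || window$t_end > sp[2] + 1e-9)
    stop(sprintf("time_normalize: window [%.3f, %.3f] exceeds series span [%.3f, %.3f]",
                 window$t_start, window$t_end, sp[1], sp[2]), call. = FALSE)
  xout <- seq(window$t_start, window$t_end, length.out = n)
  stats::approx(series_times(series), series$values, xout = xout,
                rule = 1)$y
}

#' Filter, segment and time-normalize a trial
#'
#' Applies the configured low-pass to every segment series, segments the trial
#' into steps, and time-normalizes each segment over each step window.
#'
#' @param trial a [sprint_trial()].
#' @param n_steps number of steps (default all available).
#' @param config an [analysis_config()].
#' @return list of `normalized_step` objects, each holding `step_index`, an
#'   `n_norm_points` x 7 angle matrix (`angles`), `touchdown_pct`,
#'   `flight_time`, `contact_time`, `leading_side`, `trailing_side` and the
#'   trial's `participant_id`.
#' @export
normalize_steps <- function(trial, n_steps = NULL, config = analysis_config()) {
  filtered <- filter_trial(trial, config)
  windows <- segment_steps(filtered, n_steps)
  lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    ang <- vapply(SEGMENTS, function(seg)
      time_normalize(filtered$series[[seg]], w, config$n_norm_points),
      numeric(config$n_norm_points))
    structure(
      list(step_index = w$step_index, angles = ang,
           touchdown_pct = w$touchdown_pct,
           flight_time = w$flight_time, contact_time = w$contact_time,
           leading_side = w$leading_side, trailing_side = w$trailing_side,
           participant_id = trial$participant_id),
      class = "normalized_step")
  })
}

#' Step characteristics table
#'
#' @param steps list of normalized steps from [normalize_steps()] or a
#'   `step_windows` data frame.
#' @return `data.frame` with `step`, `flight_time_s`, `contact_time_s`,
#'   `touchdown_pct`.
#' @export
step_characteristics <- function(steps) {
  if (inherits(steps, "step_windows"))
    return(data.frame(step = steps$step_index,
                      flight_time_s = steps$flight_time,
                      contact_time_s = steps$contact_time,
                      touchdown_pct = steps$touchdown_pct))
  data.frame(
    step = vapply(steps, `[[`, numeric(1), "step_index"),
    flight_time_s = vapply(steps, `[[`, numeric(1), "flight_time"),
    contact_time_s = vapply(steps, `[[`, numeric(1), "contact_time"),
    touchdown_pct = vapply(steps, `[[`, numeric(1), "touchdown_pct"))
}
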