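# Core domain types: angle series, gait events, trials, analysis configuration.

#' Segment identifiers
#'
#' The seven sagittal-plane segments carried by a trial: trunk plus left/right
#' thigh, shank and foot.
#'
#' @export
SEGMENTS <- c("trunk", "thigh_L", "thigh_R", "shank_L", "shank_R",
              "foot_L", "foot_R")

#' Construct an angle time series for one segment
#'
#' Angles are sagittal-plane segment angles in degrees, sampled uniformly.
#' The sign convention is anticlockwise-positive as viewed from the athlete's
#' right with motion left-to-right; clockwise rotation decreases the angle.
#'
#' @param segment_id one of [SEGMENTS].
#' @param values numeric vector of angles in degrees, length >= 2, all finite.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#' @return an object of class `angle_series`.
#' @export
angle_series <- function(segment_id, values, sample_rate, start_time = 0) {
  segment_id <- match.arg(segment_id, SEGMENTS)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("angle_series: 'values' must have length >= 2", call. = FALSE)
  if (!all(is.finite(values)))
    stop("angle_series: all angles must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("angle_series: 'sample_rate' must be a positive scalar", call. = FALSE)
  structure(
    list(segment_id = segment_id, values = values,
         sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = "angle_series")
}

#' Sample times of an angle series
#' @param series an `angle_series`.
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(series) {
  series$start_time + (seq_along(series$values) - 1L) / series$sample_rate
}

#' Time span of an angle series
#' @param series an `angle_series`.
#' @return numeric length-2 vector `c(first, last)` sample time in seconds.
#' @export
series_span <- function(series) {
  c(series$start_time,
    series$start_time + (length(series$values) - 1L) / series$sample_rate)
}

#' @export
print.angle_series <- function(x, ...) {
  sp <- series_span(x)
  cat(sprintf("<angle_series> %s: %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              x$segment_id, length(x$values), x$sample_rate, sp[1], sp[2]))
  invisible(x)
}

#' Construct a gait event table
#'
#' Events mark toe-offs and touchdowns on the trial clock (seconds from
#' recording start). Block clearance is the toe-off labelled `"TO_0"`.
#'
#' @param kind character vector, each `"toe_off"` or `"touchdown"`.
#' @param time_s event times in seconds.
#' @param side character vector, each `"left"` or `"right"`.
#' @param label event labels, e.g. `"TO_0"`, `"TD_1"`.
#' @return a `data.frame` of class `gait_events`, ordered by time.
#' @export
gait_events <- function(kind, time_s, side, label) {
  kind <- match.arg(kind, c("toe_off", "touchdown"), several.ok = TRUE)
  side <- match.arg(side, c("left", "right"), several.ok = TRUE)
  ev <- data.frame(kind = kind, time_s = as.numeric(time_s),
                   side = side, label = as.character(label),
                   stringsAsFactors = FALSE)
  if (anyNA(ev$time_s) || !all(is.finite(ev$time_s)))
    stop("gait_events: event times must be finite", call. = FALSE)
  if (is.unsorted(ev$time_s, strictly = TRUE))
    stop("gait_events: event times must be strictly increasing", call. = FALSE)
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Construct a sprint trial
#'
#' Bundles the seven segment angle series with the gait event annotations for
#' one sprint of one participant.
#'
#' @param participant_id participant identifier (character scalar).
#' @param series named list of `angle_series`, one per entry of [SEGMENTS].
#' @param events a [gait_events()] table.
#' @param front_block_side `"left"` or `"right"`: which foot was in the front
#'   block (its clearance, labelled `TO_0`, starts step 1).
#' @return an object of class `sprint_trial`.
#' @export
sprint_trial <- function(participant_id, series, events, front_block_side) {
  front_block_side <- match.arg(front_block_side, c("left", "right"))
  if (!inherits(events, "gait_events")) {
    events <- gait_events(events$kind, events$time_s, events$side, events$label)
  }
  ids <- vapply(series, function(s) s$segment_id, character(1))
  names(series) <- ids
  missing <- setdiff(SEGMENTS, ids)
  if (length(missing))
    stop("sprint_trial: missing segment series: ",
         paste(missing, collapse = ", "), call. = FALSE)
  # every event must lie within the span of every series
  spans <- vapply(series[SEGMENTS], series_span, numeric(2))
  lo <- max(spans[1, ]); hi <- min(spans[2, ])
  bad <- events$time_s < lo - 1e-9 | events$time_s > hi + 1e-9
  if (any(bad))
    stop(sprintf(
      "sprint_trial: event(s) %s outside the recorded span [%.3f, %.3f] s",
      paste(events$label[bad], collapse = ", "), lo, hi), call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id),
         series = series[SEGMENTS], events = events,
         front_block_side = front_block_side),
    class = "sprint_trial")
}

#' @export
print.sprint_trial <- function(x, ...) {
  cat(sprintf("<sprint_trial> participant %s: %d segments, %d events, front block %s\n",
              x$participant_id, length(x$series), nrow(x$events),
              x$front_block_side))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the coordination pipeline.
#'
#' @param n_norm_points number of points each step is time-normalized to
#'   (default 101, giving 100 coupling-angle intervals).
#' @param lowpass_cutoff low-pass cutoff in Hz applied to every angle series
#'   before segmentation (default 15). `NA` disables filtering.
#' @param filter_order Butterworth order before the forward-backward pass
#'   (default 4).
#' @param circular_sd_formula `"angular_deviation"` for sqrt(2 (1 - r)) or
#'   `"log"` for sqrt(-2 log r), both reported in degrees.
#' @param bin_boundary_rule `"distal"` assigns coupling angles on an exact
#'   quadrant diagonal (50% dominancy) to the distal-dominant bin; `"lower"`
#'   uses plain half-open `[lower, upper)` sectors of gamma.
#' @param rng_seed integer seed used by stochastic helpers.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(n_norm_points = 101L,
                            lowpass_cutoff = 15,
                            filter_order = 4L,
                            circular_sd_formula = c("angular_deviation", "log"),
                            bin_boundary_rule = c("distal", "lower"),
                            rng_seed = 1L) {
  circular_sd_formula <- match.arg(circular_sd_formula)
  bin_boundary_rule <- match.arg(bin_boundary_rule)
  n_norm_points <- as.integer(n_norm_points)
  if (is.na(n_norm_points) || n_norm_points < 3L)
    stop("analysis_config: n_norm_points must be >= 3", call. = FALSE)
  if (!is.na(lowpass_cutoff) && lowpass_cutoff <= 0)
    stop("analysis_config: lowpass_cutoff must be positive or NA", call. = FALSE)
  structure(
    list(n_norm_points = n_norm_points,
         lowpass_cutoff = as.numeric(lowpass_cutoff),
         filter_order = as.integer(filter_order),
         circular_sd_formula = circular_sd_formula,
         bin_boundary_rule = bin_boundary_rule,
         rng_seed = as.integer(rng_seed)),
    class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path path to a YAML file with keys mirroring [analysis_config()].
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}
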