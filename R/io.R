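# Readers and writers for the plain-text exchange formats: angle CSVs
# (time_s + one column per segment), event CSV/JSON files, profile exports.

ANGLE_COLUMNS <- c("time_s", SEGMENTS)

infer_sample_rate <- function(time_s) {
  dt <- diff(time_s)
  if (any(dt <= 0))
    stop("angles file: 'time_s' must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("angles file: 'time_s' must be uniformly sampled", call. = FALSE)
  1 / stats::median(dt)
}

#' Read a trial from an angles CSV and an events file
#'
#' The angles file must have a `time_s` column plus one column per segment in
#' [SEGMENTS]. The events file is either a CSV with columns
#' `kind,time_s,side,label` or a JSON array of objects with those fields.
#'
#' @param angles_path path to the angle CSV.
#' @param events_path path to the events CSV or JSON file.
#' @param participant_id participant identifier to attach; defaults to the
#'   angles file name without extension.
#' @param front_block_side front-block side; defaults to the side of the
#'   toe-off labelled `TO_0`.
#' @return a [sprint_trial()].
#' @export
read_trial <- function(angles_path, events_path,
                       participant_id = NULL, front_block_side = NULL) {
  ang <- utils::read.csv(angles_path, stringsAsFactors = FALSE)
  missing <- setdiff(ANGLE_COLUMNS, names(ang))
  if (length(missing))
    stop("read_trial: angles file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fs <- infer_sample_rate(ang$time_s)
  series <- lapply(SEGMENTS, function(seg)
    angle_series(seg, ang[[seg]], sample_rate = fs,
                 start_time = ang$time_s[1]))
  ev <- read_events(events_path)
  if (is.null(front_block_side)) {
    i0 <- which(ev$label == "TO_0")
    if (length(i0) != 1L)
      stop("read_trial: need exactly one TO_0 event to infer front_block_side",
           call. = FALSE)
    front_block_side <- ev$side[i0]
  }
  if (is.null(participant_id))
    participant_id <- tools::file_path_sans_ext(basename(angles_path))
  sprint_trial(participant_id, series, ev, front_block_side)
}

#' Read a gait events file (CSV or JSON)
#' @param path events file; format chosen by extension (`.json` vs CSV).
#' @return a [gait_events()] table.
#' @export
read_events <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path)
    if (!is.data.frame(rec)) rec <- as.data.frame(rec)
  } else {
    rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing <- setdiff(c("kind", "time_s", "side", "label"), names(rec))
  if (length(missing))
    stop("read_events: events file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  gait_events(rec$kind, rec$time_s, rec$side, rec$label)
}

#' Write a trial to an angles CSV and an events CSV
#'
#' Inverse of [read_trial()]: numeric values round-trip to at least six
#' significant figures (full double precision is written).
#'
#' @param trial a [sprint_trial()].
#' @param angles_path,events_path output paths.
#' @return invisibly, `trial`.
#' @export
write_trial <- function(trial, angles_path, events_path) {
  stopifnot(inherits(trial, "sprint_trial"))
  tm <- series_times(trial$series[[1]])
  n <- length(tm)
  ok <- vapply(trial$series, function(s)
    length(s$values) == n &&
      isTRUE(all.equal(series_times(s), tm, tolerance = 1e-9)), logical(1))
  if (!all(ok))
    stop("write_trial: all series must share one time base", call. = FALSE)
  ang <- data.frame(time_s = tm)
  for (seg in SEGMENTS) ang[[seg]] <- trial$series[[seg]]$values
  utils::write.csv(format(ang, digits = 15, trim = TRUE, scientific = FALSE),
                   angles_path, row.names = FALSE, quote = FALSE)
  ev <- as.data.frame(trial$events)
  ev$time_s <- format(ev$time_s, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  invisible(trial)
}

#' Write coordination profiles to CSV
#'
#' Long-format export: one row per coupling-angle interval with columns
#' `participant, step, coupling, interval_index, coupling_angle_deg,
#' bin_label, dominant_segment, dominancy_pct`.
#'
#' @param profiles a single `coordination_profile` or a list of them.
#' @param path output CSV path.
#' @return invisibly, the written data frame.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "coordination_profile")) profiles <- list(profiles)
  cols <- c("participant", "step", "coupling", "interval_index",
            "coupling_angle_deg", "bin_label", "dominant_segment",
            "dominancy_pct")
  if (length(profiles) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    lens <- vapply(profiles, function(p) nrow(p$intervals), integer(1))
    cps <- vapply(profiles, function(p) p$coupling, character(1))
    if (length(unique(lens)) != 1L || length(unique(cps)) != 1L)
      stop("write_profiles: profiles must share one coupling and one length",
           call. = FALSE)
    out <- do.call(rbind, lapply(profiles, function(p)
      data.frame(participant = p$participant_id, step = p$step_index,
                 coupling = p$coupling,
                 interval_index = p$intervals$interval,
                 coupling_angle_deg = p$intervals$gamma,
                 bin_label = p$intervals$bin_label,
                 dominant_segment = p$intervals$dominant_segment,
                 dominancy_pct = p$intervals$dominancy,
                 stringsAsFactors = FALSE)))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
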