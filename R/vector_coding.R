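# Modified vector coding: coupling angles from angle-angle diagrams, the
# eight-bin coordination classification, and segment dominancy.
#
# The coupling angle gamma at interval i is the direction, relative to the
# right horizontal and mapped to [0, 360), of the vector
# (proximal[i+1] - proximal[i], distal[i+1] - distal[i]) in the angle-angle
# plane (proximal on x, distal on y). The four quadrants encode in-phase (+),
# anti-phase (distal +), in-phase (-), anti-phase (proximal +); each quadrant
# splits into two 45-degree bins by dominant segment. Converting gamma to
# gradians (90 degrees = 100 gradians) expresses which segment rotates more:
# 100% dominancy means the other segment is stationary, 50% equal rotation.

#' Supported segment couplings
#' @export
COUPLINGS <- c("thigh_thigh", "trunk_shank", "shank_foot")

# wrap angles into [0, 360), guarding against x %% 360 returning 360 for
# tiny negative floating-point inputs
wrap360 <- function(x) {
  out <- x %% 360
  out[out > 360 - 1e-9] <- 0
  out
}

#' Coupling angles from paired segment sequences
#'
#' @param proximal,distal numeric vectors of equal length (n >= 2): the
#'   proximal and distal segment angle sequences in degrees.
#' @return numeric vector of n-1 coupling angles in `[0, 360)`; `NA` where
#'   both increments are exactly zero (direction undefined).
#' @export
coupling_angle <- function(proximal, distal) {
  if (length(proximal) != length(distal))
    stop("coupling_angle: sequences must have equal length", call. = FALSE)
  if (length(proximal) < 2L)
    stop("coupling_angle: need at least two points", call. = FALSE)
  dp <- diff(proximal)
  dd <- diff(distal)
  gamma <- wrap360(atan2(dd, dp) * 180 / pi)
  gamma[dp == 0 & dd == 0] <- NA_real_
  gamma
}

#' Segment dominancy from a coupling angle
#'
#' Folds gamma into `[0, 90]` and converts to gradians: the distal share is
#' `theta * 100 / 90` percent, and the reported magnitude is the dominant
#' segment's share, in `[50, 100]`. Exactly 100 on the four axes (one segment
#' stationary), exactly 50 on the four diagonals (equal rotation; the tie is
#' assigned to the distal segment).
#'
#' @param gamma coupling angle(s) in degrees, `[0, 360)`; `NA` propagates.
#' @return `data.frame` with columns `dominant` (`"proximal"`/`"distal"`) and
#'   `dominancy` (percent in `[50, 100]`).
#' @export
dominancy <- function(gamma) {
  theta <- gamma %% 180
  theta <- ifelse(theta > 90, 180 - theta, theta)
  d <- theta * 100 / 90                        # distal share in [0, 100]
  dominant <- ifelse(d >= 50, "distal", "proximal")
  dominant[is.na(gamma)] <- NA_character_
  data.frame(dominant = dominant, dominancy = pmax(d, 100 - d),
             stringsAsFactors = FALSE)
}

#' The eight-bin coordination dictionary for a coupling
#'
#' Bin indices run 0-7 anticlockwise from gamma = 0. Display names follow the
#' coupling's proximal/distal segment names (trailing/leading thighs, trunk
#' and shank, shank and foot) and the field's light/dark colour conventions
#' (dark = proximal dominant, light = distal dominant; blue = in-phase (+),
#' green = anti-phase around 135 degrees, purple = in-phase (-), red =
#' anti-phase around 315 degrees).
#'
#' @param coupling one of [COUPLINGS], or `"generic"` for proximal/distal
#'   naming.
#' @return `data.frame` with one row per bin: `bin`, `lower`, `upper`,
#'   `phase`, `direction`, `dominant`, `label`, `color`.
#' @export
bin_dictionary <- function(coupling = "generic") {
  nm <- switch(coupling,
               thigh_thigh = c("trailing", "leading"),
               trunk_shank = c("trunk", "shank"),
               shank_foot = c("shank", "foot"),
               generic = c("proximal", "distal"),
               stop("bin_dictionary: unknown coupling '", coupling, "'",
                    call. = FALSE))
  prox <- nm[1]; dist <- nm[2]
  phase <- c("in-phase", "in-phase", "anti-phase", "anti-phase",
             "in-phase", "in-phase", "anti-phase", "anti-phase")
  dominant <- c("proximal", "distal", "distal", "proximal",
                "proximal", "distal", "distal", "proximal")
  # rotation sign of the dominant segment (equals both signs for in-phase)
  direction <- c("+", "+", "+", "-", "-", "-", "-", "+")
  dom_name <- ifelse(dominant == "proximal", prox, dist)
  label <- sprintf("%s %s (%s)", phase, dom_name, direction)
  data.frame(
    bin = 0:7, lower = 45 * (0:7), upper = 45 * (1:8),
    phase = phase, direction = direction, dominant = dominant,
    label = label,
    color = c("#08519C", "#6BAED6", "#74C476", "#006D2C",
              "#54278F", "#9E9AC8", "#FB6A4A", "#A50F15"),
    stringsAsFactors = FALSE)
}

#' Classify coupling angles into coordination bins
#'
#' Quadrants encode phase and direction; within each quadrant the half nearer
#' a proximal axis is proximal dominant. Under the default boundary rule
#' (`"distal"`), an angle on an exact diagonal (50% dominancy) goes to the
#' distal-dominant bin of its quadrant, keeping the bin's dominant segment
#' consistent with [dominancy()]; `"lower"` instead uses plain half-open
#' `[lower, upper)` sectors.
#'
#' @param gamma coupling angle(s) in degrees, `[0, 360)`; `NA` propagates.
#' @param rule boundary rule, `"distal"` (default) or `"lower"`.
#' @return integer bin indices in 0-7 (`NA` where gamma is undefined).
#' @export
classify_bin <- function(gamma, rule = c("distal", "lower")) {
  rule <- match.arg(rule)
  g <- wrap360(gamma)
  if (rule == "lower") return(as.integer(g %/% 45))
  quadrant <- as.integer(g %/% 90)             # 0..3
  dom <- dominancy(g)$dominant
  # within-quadrant order of (proximal, distal) bins alternates by quadrant
  first_is_proximal <- quadrant %% 2L == 0L
  offset <- ifelse(first_is_proximal,
                   ifelse(dom == "proximal", 0L, 1L),
                   ifelse(dom == "distal", 0L, 1L))
  out <- quadrant * 2L + offset
  out[is.na(gamma)] <- NA_integer_
  as.integer(out)
}

# resolve a coupling's proximal/distal segment columns for one step.
# Intra-limb couplings use the limb in stance during the step, i.e. the
# leading limb (it touches down within the step).
coupling_segments <- function(coupling, step) {
  coupling <- match.arg(coupling, COUPLINGS)
  lead <- step$leading_side
  trail <- step$trailing_side
  sfx <- function(side) if (side == "left") "L" else "R"
  switch(coupling,
         thigh_thigh = c(proximal = paste0("thigh_", sfx(trail)),
                         distal = paste0("thigh_", sfx(lead))),
         trunk_shank = c(proximal = "trunk",
                         distal = paste0("shank_", sfx(lead))),
         shank_foot = c(proximal = paste0("shank_", sfx(lead)),
                        distal = paste0("foot_", sfx(lead))))
}

#' Build a coordination profile for one step and coupling
#'
#' Composes [coupling_angle()], [classify_bin()] and [dominancy()] per
#' normalized-time interval. Intervals where both segments are exactly still
#' (undefined gamma) inherit the previous defined bin when one exists (flagged
#' `inherited`), otherwise stay undefined and are excluded from bin counts.
#'
#' @param step a `normalized_step` from [normalize_steps()].
#' @param coupling one of [COUPLINGS].
#' @param config an [analysis_config()] (boundary rule).
#' @return an object of class `coordination_profile`: list with
#'   `participant_id`, `step_index`, `coupling`, `touchdown_pct`, `segments`
#'   (resolved proximal/distal segment ids) and `intervals`, a data frame with
#'   one row per interval (`interval`, `pct`, `gamma`, `bin`, `bin_label`,
#'   `color`, `phase`, `dominant`, `dominant_segment`, `dominancy`,
#'   `defined`, `inherited`).
#' @export
build_profile <- function(step, coupling, config = analysis_config()) {
  stopifnot(inherits(step, "normalized_step"))
  coupling <- match.arg(coupling, COUPLINGS)
  segs <- coupling_segments(coupling, step)
  missing <- setdiff(segs, colnames(step$angles))
  if (length(missing))
    stop("build_profile: step is missing segment(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  gamma <- coupling_angle(step$angles[, segs["proximal"]],
                          step$angles[, segs["distal"]])
  bin <- classify_bin(gamma, config$bin_boundary_rule)
  dom <- dominancy(gamma)
  defined <- !is.na(gamma)
  inherited <- rep(FALSE, length(gamma))
  if (any(!defined) && any(defined)) {
    filled <- bin
    for (i in seq_along(filled)) {
      if (is.na(filled[i]) && i > 1L && !is.na(filled[i - 1L])) {
        filled[i] <- filled[i - 1L]
        inherited[i] <- TRUE
      }
    }
    bin <- filled
  }
  dict <- bin_dictionary(coupling)
  n <- length(gamma)
  role_names <- setNames(c("proximal", "distal"), segs)
  dominant_segment <- segs[match(dom$dominant, c("proximal", "distal"))]
  intervals <- data.frame(
    interval = seq_len(n),
    pct = 100 * seq_len(n) / n,
    gamma = gamma,
    bin = bin,
    bin_label = ifelse(is.na(bin), NA_character_, dict$label[bin + 1L]),
    color = ifelse(is.na(bin), NA_character_, dict$color[bin + 1L]),
    phase = ifelse(is.na(bin), NA_character_, dict$phase[bin + 1L]),
    dominant = dom$dominant,
    dominant_segment = unname(dominant_segment),
    dominancy = dom$dominancy,
    defined = defined,
    inherited = inherited,
    stringsAsFactors = FALSE)
  structure(
    list(participant_id = step$participant_id, step_index = step$step_index,
         coupling = coupling, touchdown_pct = step$touchdown_pct,
         segments = segs, intervals = intervals),
    class = "coordination_profile")
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf("<coordination_profile> %s step %d, %s (%s/%s): %d intervals, %d defined\n",
              x$participant_id, x$step_index, x$coupling,
              x$segments["proximal"], x$segments["distal"],
              nrow(x$intervals), sum(x$intervals$defined)))
  invisible(x)
}

#' Build profiles for a whole trial
#'
#' @param trial a [sprint_trial()].
#' @param coupling one of [COUPLINGS] or `"all"`.
#' @param n_steps number of steps (default all).
#' @param config an [analysis_config()].
#' @return list of `coordination_profile` objects (steps nested within
#'   couplings).
#' @export
trial_profiles <- function(trial, coupling = "all", n_steps = NULL,
                           config = analysis_config()) {
  couplings <- if (identical(coupling, "all")) COUPLINGS
               else match.arg(coupling, COUPLINGS)
  steps <- normalize_steps(trial, n_steps, config)
  out <- list()
  for (cp in couplings)
    for (st in steps)
      out[[length(out) + 1L]] <- build_profile(st, cp, config)
  out
}
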