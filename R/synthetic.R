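# Synthetic multi-step sprint kinematics with known coordination ground truth.
#
# Waveforms are piecewise cosine-ease segments anchored at event-time targets
# rather than a mechanistic simulation: enough to carry the coordination
# structure the analysis assumes (oscillatory anti-phase thighs with a
# controllable trailing/leading angular-velocity ratio, trunk rotation
# reversals around touchdown, early-stance dorsiflexion followed by
# foot-driven plantarflexion) without modelling dynamics. Within each step
# both thighs follow one shared ease shape, so the trailing/leading increment
# ratio — and hence the coupling angle and dominancy — is exactly constant
# across the step, giving a closed-form ground truth.

#' Simulation configuration
#'
#' Defaults emulate the magnitudes of initial sprint acceleration in trained
#' sprinters: 4 steps at 200 Hz, flight times growing from ~80 ms and contact
#' times shrinking from ~190 ms across steps, thigh oscillation of ~70 deg per
#' step with trailing-leg dominance, stepwise trunk and shank verticalization,
#' and a progressively flatter foot at touchdown.
#'
#' @param n_participants cohort size (default 21).
#' @param n_steps steps per trial (default 4).
#' @param sample_rate sampling rate in Hz (default 200).
#' @param front_block_side which foot starts in the front block.
#' @param flight_mean,contact_mean per-step means in seconds (recycled to
#'   `n_steps`).
#' @param flight_sd,contact_sd between-participant SDs of the step timing.
#' @param thigh_rise trailing-thigh rotation per step in degrees.
#' @param thigh_ratio trailing/leading angular-velocity ratio (> 0; 1 gives
#'   pure symmetric anti-phase, 50% dominancy everywhere).
#' @param thigh_lead0,thigh_trail0 thigh angles at block clearance (leading =
#'   rear-block thigh, flexed forward; trailing = front-block thigh, extended).
#' @param trunk_start trunk angle at block clearance in degrees (from the
#'   right horizontal; 90 = upright).
#' @param trunk_flight_dip clockwise trunk rotation during flight (deg).
#' @param trunk_step_increment per-step trunk verticalization (deg); the
#'   step effect targeted by the repeated-measures ANOVA power checks.
#' @param shank_td per-step stance-shank touchdown angles (deg, recycled).
#' @param shank_to stance-shank toe-off angle (deg).
#' @param foot_td per-step stance-foot touchdown angles (deg, recycled).
#' @param foot_to per-step stance-foot toe-off angles (deg, recycled).
#' @param foot_flat foot angle at the dorsiflexion peak (deg, near flat).
#' @param dorsiflexion_frac when the dorsiflexion peak occurs, as a fraction
#'   of contact time.
#' @param noise_sd SD in degrees of additive smooth noise (band-limited below
#'   30 Hz, applied before any analysis filtering).
#' @param jitter named list of between-participant SDs:
#'   `thigh_ratio`, `thigh_rise`, `trunk_start`, `trunk_step_increment`,
#'   `angle` (applied to shank/foot anchor targets). Set all to zero (and
#'   `noise_sd = 0`) for an identical cohort.
#' @param rng_seed integer seed; trials are deterministic given
#'   `(rng_seed, participant_index)`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 21L,
                       n_steps = 4L,
                       sample_rate = 200,
                       front_block_side = "right",
                       flight_mean = c(0.08, 0.09, 0.10, 0.11),
                       contact_mean = c(0.19, 0.18, 0.17, 0.16),
                       flight_sd = 0.01,
                       contact_sd = 0.012,
                       thigh_rise = 70,
                       thigh_ratio = 1.45,
                       thigh_lead0 = -45,
                       thigh_trail0 = -105,
                       trunk_start = 25,
                       trunk_flight_dip = 5,
                       trunk_step_increment = 6,
                       shank_td = c(50, 58, 63, 66),
                       shank_to = 35,
                       foot_td = c(-35, -18, -12, -10),
                       foot_to = c(-55, -45, -45, -45),
                       foot_flat = -4,
                       dorsiflexion_frac = 0.35,
                       noise_sd = 0.5,
                       jitter = list(),
                       rng_seed = 1L) {
  front_block_side <- match.arg(front_block_side, c("left", "right"))
  jdef <- list(thigh_ratio = 0.12, thigh_rise = 4, trunk_start = 4,
               trunk_step_increment = 1.2, angle = 2.5)
  unknown <- setdiff(names(jitter), names(jdef))
  if (length(unknown))
    stop("sim_config: unknown jitter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  jdef[names(jitter)] <- jitter
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_steps = as.integer(n_steps),
    sample_rate = sample_rate, front_block_side = front_block_side,
    flight_mean = rep_len(flight_mean, n_steps),
    contact_mean = rep_len(contact_mean, n_steps),
    flight_sd = flight_sd, contact_sd = contact_sd,
    thigh_rise = thigh_rise, thigh_ratio = thigh_ratio,
    thigh_lead0 = thigh_lead0, thigh_trail0 = thigh_trail0,
    trunk_start = trunk_start, trunk_flight_dip = trunk_flight_dip,
    trunk_step_increment = trunk_step_increment,
    shank_td = rep_len(shank_td, n_steps), shank_to = shank_to,
    foot_td = rep_len(foot_td, n_steps), foot_to = rep_len(foot_to, n_steps),
    foot_flat = foot_flat, dorsiflexion_frac = dorsiflexion_frac,
    noise_sd = noise_sd, jitter = jdef, rng_seed = as.integer(rng_seed))
  if (any(cfg$flight_mean <= 0) || any(cfg$contact_mean <= 0))
    stop("sim_config: step durations must be positive", call. = FALSE)
  if (cfg$thigh_ratio <= 0)
    stop("sim_config: thigh_ratio must be positive", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("sim_config: noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# cosine-ease interpolation through anchor points (zero slope at anchors;
# constant extrapolation outside the anchor range)
anchor_eval <- function(t, at, av) {
  stopifnot(length(at) == length(av), !is.unsorted(at, strictly = TRUE))
  out <- numeric(length(t))
  out[t <= at[1]] <- av[1]
  out[t >= at[length(at)]] <- av[length(av)]
  for (j in seq_len(length(at) - 1L)) {
    idx <- t > at[j] & t < at[j + 1L]
    if (!any(idx)) next
    tau <- (t[idx] - at[j]) / (at[j + 1L] - at[j])
    out[idx] <- av[j] + (av[j + 1L] - av[j]) * (1 - cos(pi * tau)) / 2
  }
  out
}

# run fn with a deterministic, locally scoped RNG state
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

participant_seed <- function(rng_seed, participant_index) {
  (as.numeric(rng_seed) * 48271 + participant_index * 7919) %% 2147483647
}

# band-limited (< 30 Hz) smooth noise, unit SD target before scaling
smooth_noise <- function(n, fs, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n + 80L)
  cutoff <- min(30, 0.45 * fs)
  ba <- butter_lowpass(2L, cutoff / (fs / 2))
  f <- filtfilt_butter(ba$b, ba$a, w)[41:(40L + n)]
  f * sd / stats::sd(f)
}

#' Generate one synthetic sprint trial
#'
#' Deterministic given `(config$rng_seed, participant_index)`. The returned
#' trial carries a `truth` attribute recording the per-participant parameters
#' actually drawn (thigh rise/drop per step, anchor tables, event times), from
#' which the generator-implied coordination ground truth can be computed.
#'
#' @param config a [sim_config()].
#' @param participant_index 1-based participant number.
#' @return a [sprint_trial()] with attribute `truth`.
#' @export
generate_trial <- function(config, participant_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(participant_seed(config$rng_seed, participant_index),
                  function() generate_trial_impl(config, participant_index))
}

generate_trial_impl <- function(cfg, pidx) {
  ns <- cfg$n_steps
  j <- cfg$jitter
  flight <- pmax(0.03, cfg$flight_mean + stats::rnorm(ns, 0, cfg$flight_sd))
  contact <- pmax(0.06, cfg$contact_mean + stats::rnorm(ns, 0, cfg$contact_sd))
  ratio <- max(0.4, cfg$thigh_ratio + stats::rnorm(1, 0, j$thigh_ratio))
  rise <- max(20, cfg$thigh_rise + stats::rnorm(1, 0, j$thigh_rise))
  trunk0 <- cfg$trunk_start + stats::rnorm(1, 0, j$trunk_start)
  trunk_inc <- cfg$trunk_step_increment +
    stats::rnorm(1, 0, j$trunk_step_increment)
  shank_td <- cfg$shank_td + stats::rnorm(ns, 0, j$angle)
  foot_td <- cfg$foot_td + stats::rnorm(ns, 0, j$angle)
  foot_to <- cfg$foot_to + stats::rnorm(ns, 0, j$angle)

  lead_in <- 0.10; tail <- 0.10
  fs <- cfg$sample_rate
  # snap event times to the sample grid so that no sampling interval straddles
  # a step boundary: the generator's within-step increment ratios then survive
  # sampling + linear time-normalization exactly (closed-form ground truth)
  snap <- function(x) round(x * fs) / fs
  flight <- pmax(2 / fs, snap(flight))
  contact <- pmax(2 / fs, snap(contact))
  to_times <- numeric(ns + 1L); td_times <- numeric(ns)
  to_times[1] <- snap(lead_in)
  for (k in seq_len(ns)) {
    td_times[k] <- to_times[k] + flight[k]
    to_times[k + 1L] <- td_times[k] + contact[k]
  }
  duration <- to_times[ns + 1L] + tail
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  if (td_times[1] - to_times[1] < 2 / fs)
    stop("generate_trial: infeasible timing: flight shorter than two samples",
         call. = FALSE)

  sides <- c("left", "right")
  other <- function(s) if (s == "left") "right" else "left"

  # --- thighs: shared ease shape per step, exact increment ratio -----------
  drop <- rise / ratio
  thigh <- list(left = numeric(n), right = numeric(n))
  roles1 <- assign_limb_roles(1L, cfg$front_block_side)
  cur <- list()
  cur[[roles1$trailing]] <- cfg$thigh_trail0
  cur[[roles1$leading]] <- cfg$thigh_lead0
  thigh$left[] <- cur$left; thigh$right[] <- cur$right
  for (k in seq_len(ns)) {
    roles <- assign_limb_roles(k, cfg$front_block_side)
    t0 <- to_times[k]; t1 <- to_times[k + 1L]
    idx <- t >= t0
    tau <- pmin(1, pmax(0, (t[idx] - t0) / (t1 - t0)))
    s <- (1 - cos(pi * tau)) / 2
    thigh[[roles$trailing]][idx] <- cur[[roles$trailing]] + rise * s
    thigh[[roles$leading]][idx] <- cur[[roles$leading]] - drop * s
    cur[[roles$trailing]] <- cur[[roles$trailing]] + rise
    cur[[roles$leading]] <- cur[[roles$leading]] - drop
  }

  # --- trunk: clockwise in flight, anticlockwise in stance -----------------
  trunk_at <- c(0)
  trunk_av <- c(trunk0)
  a <- trunk0
  for (k in seq_len(ns)) {
    trunk_at <- c(trunk_at, to_times[k], td_times[k])
    trunk_av <- c(trunk_av, a, a - cfg$trunk_flight_dip)
    a <- a + trunk_inc
  }
  trunk_at <- c(trunk_at, to_times[ns + 1L], duration)
  trunk_av <- c(trunk_av, a, a)
  # drop the duplicated first anchor (t = 0 vs TO_0 share the start value)
  trunk_vals <- anchor_eval(t, trunk_at[-2], trunk_av[-2])

  # --- shank and foot per side: anchored at own stance events --------------
  shank <- list(); foot <- list()
  for (s in sides) {
    own <- which(vapply(seq_len(ns), function(k)
      assign_limb_roles(k, cfg$front_block_side)$leading == s, logical(1)))
    s_at <- 0; s_av <- shank_td[if (length(own)) own[1] else 1] - 15
    f_at <- 0; f_av <- foot_td[if (length(own)) own[1] else 1] - 10
    for (k in own) {
      s_at <- c(s_at, td_times[k], to_times[k + 1L])
      s_av <- c(s_av, shank_td[k], cfg$shank_to)
      t_pre <- td_times[k] - 0.3 * flight[k]
      t_dorsi <- td_times[k] + cfg$dorsiflexion_frac * contact[k]
      f_at <- c(f_at, t_pre, td_times[k], t_dorsi, to_times[k + 1L])
      f_av <- c(f_av, foot_td[k] + 8, foot_td[k], cfg$foot_flat, foot_to[k])
    }
    s_at <- c(s_at, duration); s_av <- c(s_av, s_av[length(s_av)])
    f_at <- c(f_at, duration); f_av <- c(f_av, f_av[length(f_av)])
    shank[[s]] <- anchor_eval(t, s_at, s_av)
    foot[[s]] <- anchor_eval(t, f_at, f_av)
  }

  values <- list(trunk = trunk_vals,
                 thigh_L = thigh$left, thigh_R = thigh$right,
                 shank_L = shank$left, shank_R = shank$right,
                 foot_L = foot$left, foot_R = foot$right)
  for (seg in names(values))
    values[[seg]] <- values[[seg]] + smooth_noise(n, fs, cfg$noise_sd)

  series <- lapply(names(values), function(seg)
    angle_series(seg, values[[seg]], sample_rate = fs, start_time = 0))

  ev_kind <- c("toe_off")
  ev_time <- c(to_times[1])
  ev_side <- c(cfg$front_block_side)
  ev_label <- c("TO_0")
  for (k in seq_len(ns)) {
    roles <- assign_limb_roles(k, cfg$front_block_side)
    ev_kind <- c(ev_kind, "touchdown", "toe_off")
    ev_time <- c(ev_time, td_times[k], to_times[k + 1L])
    ev_side <- c(ev_side, roles$leading, roles$leading)
    ev_label <- c(ev_label, sprintf("TD_%d", k), sprintf("TO_%d", k))
  }
  events <- gait_events(ev_kind, ev_time, ev_side, ev_label)

  trial <- sprint_trial(sprintf("P%02d", pidx), series, events,
                        cfg$front_block_side)
  attr(trial, "truth") <- list(
    participant_index = pidx, thigh_rise = rise, thigh_drop = drop,
    thigh_ratio = ratio, flight = flight, contact = contact,
    to_times = to_times, td_times = td_times,
    trunk_increment = trunk_inc,
    # closed-form thigh-thigh coordination implied by the shared ease shape:
    # gamma = atan2(-drop, rise) mod 360, constant over every step
    thigh_gamma = (atan2(-drop, rise) * 180 / pi) %% 360)
  trial
}

#' Generate a synthetic cohort
#'
#' @param config a [sim_config()].
#' @return list of `n_participants` trials (see [generate_trial()]),
#'   reproducible from `config$rng_seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_participants >= 1L)
  lapply(seq_len(config$n_participants), function(i)
    generate_trial(config, i))
}

#' Generator-implied ground truth for a trial
#'
#' @param trial a trial from [generate_trial()].
#' @return the `truth` attribute (parameters actually drawn, event times and
#'   the closed-form thigh-thigh coupling angle).
#' @export
generator_truth <- function(trial) {
  tr <- attr(trial, "truth")
  if (is.null(tr))
    stop("generator_truth: trial was not produced by generate_trial",
         call. = FALSE)
  tr
}

#' Write a synthetic cohort to a directory
#'
#' Emits the same CSV angle/event files [read_trial()] consumes
#' (`P01_angles.csv`, `P01_events.csv`, ...) plus a `manifest.json` recording
#' the configuration and per-participant seeds.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- generate_cohort(config)
  files <- lapply(trials, function(tr) {
    ap <- file.path(dir, paste0(tr$participant_id, "_angles.csv"))
    ep <- file.path(dir, paste0(tr$participant_id, "_events.csv"))
    write_trial(tr, ap, ep)
    list(participant = tr$participant_id,
         angles = basename(ap), events = basename(ep),
         seed = participant_seed(config$rng_seed,
                                 generator_truth(tr)$participant_index))
  })
  manifest <- list(package = "sprintcoord",
                   config = unclass(config)[setdiff(names(config), "jitter")],
                   jitter = config$jitter, files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json` (or matching
#'   `*_angles.csv` / `*_events.csv` pairs).
#' @return list of [sprint_trial()]s.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::fromJSON(mf, simplifyDataFrame = FALSE)
    return(lapply(manifest$files, function(f)
      read_trial(file.path(dir, f$angles), file.path(dir, f$events),
                 participant_id = f$participant)))
  }
  angles <- sort(Sys.glob(file.path(dir, "*_angles.csv")))
  if (!length(angles))
    stop("read_cohort: no manifest.json or *_angles.csv files in ", dir,
         call. = FALSE)
  lapply(angles, function(ap) {
    ep <- sub("_angles\\.csv$", "_events.csv", ap)
    read_trial(ap, ep,
               participant_id = sub("_angles$", "",
                                    tools::file_path_sans_ext(basename(ap))))
  })
}
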