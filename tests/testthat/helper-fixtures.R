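# Fixtures built in code: a small hand-specified trial matching the canonical
# two-step event layout, and an independent sign/magnitude bin classifier used
# as the oracle for vector coding.

# events: TO_0(right)@0.00, TD_1(left)@0.32, TO_1(left)@0.52,
#         TD_2(right)@0.60, TO_2(right)@0.79
fixture_events <- function() {
  gait_events(kind = c("toe_off", "touchdown", "toe_off", "touchdown",
                       "toe_off"),
              time_s = c(0.00, 0.32, 0.52, 0.60, 0.79),
              side = c("right", "left", "left", "right", "right"),
              label = c("TO_0", "TD_1", "TO_1", "TD_2", "TO_2"))
}

# trial sampled at 100 Hz over [0, 1] s; per-segment values given by
# functions of time (default: distinct linear ramps)
fixture_trial <- function(fns = list(), fs = 100, duration = 1,
                          events = fixture_events(),
                          front_block_side = "right") {
  t <- seq(0, duration, by = 1 / fs)
  series <- lapply(seq_along(SEGMENTS), function(i) {
    seg <- SEGMENTS[i]
    f <- if (!is.null(fns[[seg]])) fns[[seg]] else function(t) i * 10 + 5 * t
    angle_series(seg, f(t), sample_rate = fs, start_time = 0)
  })
  sprint_trial("T01", series, events, front_block_side)
}

# a normalized_step built directly from per-segment sequences (bypasses
# segmentation; for unit tests of vector coding)
fixture_step <- function(angles, step_index = 1, leading_side = "left",
                         touchdown_pct = 61.5) {
  n <- length(angles[[1]])
  mat <- matrix(0, n, length(SEGMENTS), dimnames = list(NULL, SEGMENTS))
  for (seg in names(angles)) mat[, seg] <- angles[[seg]]
  structure(
    list(step_index = step_index, angles = mat,
         touchdown_pct = touchdown_pct, flight_time = 0.32,
         contact_time = 0.20, leading_side = leading_side,
         trailing_side = if (leading_side == "left") "right" else "left",
         participant_id = "T01"),
    class = "normalized_step")
}

# independent bin classifier from increment signs and magnitudes (never
# computes a coupling angle); NA where both increments are zero
oracle_bins_from_increments <- function(dp, dd) {
  quadrant <- ifelse(dp > 0 & dd >= 0, 0L,
              ifelse(dp <= 0 & dd > 0, 1L,
              ifelse(dp < 0 & dd <= 0, 2L, 3L)))
  distal_dom <- abs(dd) >= abs(dp)
  bin <- integer(length(dp))
  first_is_proximal <- quadrant %% 2L == 0L
  bin <- quadrant * 2L +
    ifelse(first_is_proximal, ifelse(distal_dom, 1L, 0L),
           ifelse(distal_dom, 0L, 1L))
  bin[dp == 0 & dd == 0] <- NA_integer_
  as.integer(bin)
}

# oracle bins for a normalized step + coupling, straight from the segment
# increments of the generated series (the generator-implied slopes)
oracle_bins_for_step <- function(step, coupling) {
  segs <- switch(coupling,
                 thigh_thigh = c(
                   paste0("thigh_", ifelse(step$trailing_side == "left", "L", "R")),
                   paste0("thigh_", ifelse(step$leading_side == "left", "L", "R"))),
                 trunk_shank = c(
                   "trunk",
                   paste0("shank_", ifelse(step$leading_side == "left", "L", "R"))),
                 shank_foot = c(
                   paste0("shank_", ifelse(step$leading_side == "left", "L", "R")),
                   paste0("foot_", ifelse(step$leading_side == "left", "L", "R"))))
  dp <- diff(step$angles[, segs[1]])
  dd <- diff(step$angles[, segs[2]])
  oracle_bins_from_increments(dp, dd)
}

noise_free_config <- function(...) {
  sim_config(noise_sd = 0, flight_sd = 0.008, contact_sd = 0.008, ...)
}
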