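# Group-level coordination description: circular mean profiles,
# between-individual circular SD, bin frequencies, and the CA_Diff
# step-to-step similarity score.

#' Circular mean and mean resultant length
#'
#' @param angles angles in degrees; `NA`s dropped with `na.rm = TRUE`.
#' @param na.rm drop undefined angles (default `TRUE`).
#' @return list with `mean` (degrees in `[0, 360)`, `NA` when r is 0 or no
#'   angle is defined) and `r` (mean resultant length in `[0, 1]`).
#' @export
circular_mean <- function(angles, na.rm = TRUE) {
  if (na.rm) angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) return(list(mean = NA_real_, r = NA_real_))
  rad <- angles * pi / 180
  C <- mean(cos(rad)); S <- mean(sin(rad))
  r <- sqrt(C^2 + S^2)
  m <- if (r < 1e-12) NA_real_ else wrap360(atan2(S, C) * 180 / pi)
  list(mean = m, r = r)
}

#' Circular standard deviation from a mean resultant length
#'
#' @param r mean resultant length(s) in `[0, 1]`.
#' @param formula `"angular_deviation"` for sqrt(2 (1 - r)) (default) or
#'   `"log"` for sqrt(-2 log r).
#' @return circular SD in degrees.
#' @export
circular_sd <- function(r, formula = c("angular_deviation", "log")) {
  formula <- match.arg(formula)
  rad <- switch(formula,
                angular_deviation = sqrt(2 * (1 - r)),
                log = sqrt(-2 * log(pmax(r, .Machine$double.xmin))))
  rad * 180 / pi
}

#' Group coordination profile from per-participant profiles
#'
#' Pointwise circular mean coupling angle, mean resultant length, circular SD
#' (between-individual variation), and the mean profile's bin and dominancy
#' (classified from the circular mean angle, as mean profiles are displayed).
#'
#' @param profiles list of `coordination_profile`s for the same coupling and
#'   step across participants (>= 2 for a defined SD).
#' @param config an [analysis_config()] (SD formula, boundary rule).
#' @return `data.frame` of class `group_profile`: per interval `interval`,
#'   `pct`, `n`, `mean_deg`, `r`, `sd_deg`, `mean_bin`, `mean_bin_label`,
#'   `mean_dominancy`; attributes `coupling`, `step_index`,
#'   `mean_touchdown_pct`.
#' @export
group_profile <- function(profiles, config = analysis_config()) {
  stopifnot(length(profiles) >= 1L)
  cps <- unique(vapply(profiles, `[[`, character(1), "coupling"))
  if (length(cps) != 1L)
    stop("group_profile: profiles must share one coupling", call. = FALSE)
  lens <- unique(vapply(profiles, function(p) nrow(p$intervals), integer(1)))
  if (length(lens) != 1L)
    stop("group_profile: profiles must share one normalization length",
         call. = FALSE)
  gm <- vapply(profiles, function(p) p$intervals$gamma, numeric(lens))
  gm <- matrix(gm, nrow = lens)
  stats_i <- apply(gm, 1L, circular_mean)
  mean_deg <- vapply(stats_i, `[[`, numeric(1), "mean")
  r <- vapply(stats_i, `[[`, numeric(1), "r")
  n_def <- rowSums(!is.na(gm))
  sd_deg <- ifelse(n_def >= 2L, circular_sd(r, config$circular_sd_formula),
                   NA_real_)
  mean_bin <- classify_bin(mean_deg, config$bin_boundary_rule)
  dict <- bin_dictionary(cps)
  out <- data.frame(
    interval = seq_len(lens), pct = 100 * seq_len(lens) / lens,
    n = n_def, mean_deg = mean_deg, r = r, sd_deg = sd_deg,
    mean_bin = mean_bin,
    mean_bin_label = ifelse(is.na(mean_bin), NA_character_,
                            dict$label[mean_bin + 1L]),
    mean_dominancy = dominancy(mean_deg)$dominancy,
    stringsAsFactors = FALSE)
  attr(out, "coupling") <- cps
  attr(out, "step_index") <- unique(vapply(profiles, `[[`, numeric(1),
                                           "step_index"))
  attr(out, "mean_touchdown_pct") <-
    mean(vapply(profiles, `[[`, numeric(1), "touchdown_pct"))
  class(out) <- c("group_profile", "data.frame")
  out
}

#' Between-individual circular SD profile
#'
#' Convenience wrapper returning only the pointwise circular SD curve.
#'
#' @inheritParams group_profile
#' @return numeric vector of per-interval circular SDs in degrees (`NA` where
#'   fewer than two participants are defined).
#' @export
circular_sd_profile <- function(profiles, config = analysis_config()) {
  group_profile(profiles, config)$sd_deg
}

#' Coordination bin frequencies for one profile
#'
#' Percentage of defined intervals (including inherited ones) falling in each
#' of the eight bins; sums to 100 exactly.
#'
#' @param profile a `coordination_profile`.
#' @return named numeric vector of length 8 (names `bin0`..`bin7`).
#' @export
bin_frequencies <- function(profile) {
  stopifnot(inherits(profile, "coordination_profile"))
  bins <- profile$intervals$bin
  bins <- bins[!is.na(bins)]
  if (length(bins) == 0L)
    stop("bin_frequencies: profile has no defined intervals", call. = FALSE)
  counts <- tabulate(bins + 1L, nbins = 8L)
  setNames(100 * counts / length(bins), paste0("bin", 0:7))
}

#' Long-format bin frequency table across profiles
#'
#' @param profiles list of `coordination_profile`s.
#' @return `data.frame` with `participant`, `coupling`, `step`, `bin`,
#'   `bin_label`, `freq_pct`.
#' @export
bin_frequency_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    f <- bin_frequencies(p)
    dict <- bin_dictionary(p$coupling)
    data.frame(participant = p$participant_id, coupling = p$coupling,
               step = p$step_index, bin = 0:7, bin_label = dict$label,
               freq_pct = unname(f), stringsAsFactors = FALSE)
  }))
}

#' Coupling-angle difference score (CA_Diff) between two bin sequences
#'
#' Per interval, the distance between the two bins on the eight-bin ring
#' (0 = same bin, 4 = diametrically opposite); the sum is expressed as a
#' percentage of the maximum possible (4 per compared interval). Lower scores
#' mean more similar coordination. Intervals undefined in either sequence are
#' excluded from numerator and denominator.
#'
#' @param bins_a,bins_b integer bin sequences (0-7) of equal length, or
#'   `coordination_profile`s.
#' @return list with `score` (percent in `[0, 100]`), `n_compared`, and
#'   `distances` (per-interval ring distances).
#' @export
ca_diff <- function(bins_a, bins_b) {
  if (inherits(bins_a, "coordination_profile")) bins_a <- bins_a$intervals$bin
  if (inherits(bins_b, "coordination_profile")) bins_b <- bins_b$intervals$bin
  if (length(bins_a) != length(bins_b))
    stop("ca_diff: bin sequences must have equal length", call. = FALSE)
  d <- bin_ring_distance(bins_a, bins_b)
  ok <- !is.na(d)
  if (!any(ok))
    stop("ca_diff: no interval is defined in both sequences", call. = FALSE)
  list(score = 100 * sum(d[ok]) / (4 * sum(ok)), n_compared = sum(ok),
       distances = d)
}

#' Ring distance between coordination bins
#'
#' @param a,b integer bin indices in 0-7 (vectors recycle as usual).
#' @return integer distances in 0-4 (`NA` where either bin is `NA`).
#' @export
bin_ring_distance <- function(a, b) {
  k <- abs(a - b)
  pmin(k, 8L - k)
}

#' CA_Diff table across consecutive steps
#'
#' Compares each participant's step k to step k+1 within each coupling, then
#' appends group mean and SD rows per step pair.
#'
#' @param profiles list of `coordination_profile`s (several steps per
#'   participant).
#' @return `data.frame` with `participant`, `coupling`, `step_pair`,
#'   `score_pct`; group summaries in `attr(, "summary")` with
#'   `mean_pct`, `sd_pct` per coupling and step pair.
#' @export
ca_diff_table <- function(profiles) {
  key <- data.frame(
    participant = vapply(profiles, `[[`, character(1), "participant_id"),
    coupling = vapply(profiles, `[[`, character(1), "coupling"),
    step = vapply(profiles, `[[`, numeric(1), "step_index"),
    idx = seq_along(profiles), stringsAsFactors = FALSE)
  rows <- list()
  for (pc in split(key, list(key$participant, key$coupling), drop = TRUE)) {
    pc <- pc[order(pc$step), ]
    if (nrow(pc) < 2L) next
    for (i in seq_len(nrow(pc) - 1L)) {
      if (pc$step[i + 1L] != pc$step[i] + 1L) next
      sc <- ca_diff(profiles[[pc$idx[i]]], profiles[[pc$idx[i + 1L]]])$score
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pc$participant[1], coupling = pc$coupling[1],
        step_pair = sprintf("S%d-S%d", pc$step[i], pc$step[i + 1L]),
        score_pct = sc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("ca_diff_table: no consecutive step pairs found", call. = FALSE)
  agg_m <- stats::aggregate(score_pct ~ coupling + step_pair, out, mean)
  agg_s <- stats::aggregate(score_pct ~ coupling + step_pair, out, stats::sd)
  summary <- data.frame(coupling = agg_m$coupling, step_pair = agg_m$step_pair,
                        mean_pct = agg_m$score_pct, sd_pct = agg_s$score_pct,
                        stringsAsFactors = FALSE)
  summary$formatted <- sprintf("%s=%.1f±%.1f%%", summary$step_pair,
                               summary$mean_pct, summary$sd_pct)
  attr(out, "summary") <- summary
  out
}
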