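# Publication-style coordination plots: dominancy-height bars coloured by
# bin, between-individual SD curves, bin-frequency heat tables. All plots are
# drawn headlessly with base graphics at fixed sizes, with no timestamps.

open_device <- function(out, width = 9, height = 4.5) {
  ext <- tolower(tools::file_ext(out))
  switch(ext,
         png = grDevices::png(out, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(out, width = width, height = height),
         stop("plot: unsupported output format '", ext, "' (use png or svg)",
              call. = FALSE))
}

draw_profile_panel <- function(pct, dominancy, color, touchdown_pct,
                               main = "", crossover_pct = NULL) {
  graphics::plot(NULL, xlim = c(0, 100), ylim = c(50, 100), xaxs = "i",
                 yaxs = "i", xlab = "normalized time (%)",
                 ylab = "segment dominancy (%)", main = main)
  graphics::rect(touchdown_pct, 50, 100, 100, col = "#00000022", border = NA)
  w <- if (length(pct) > 1L) diff(pct[1:2]) else 1
  graphics::rect(pct - w, 50, pct, dominancy,
                 col = ifelse(is.na(color), "#DDDDDD", color), border = NA)
  if (!is.null(crossover_pct) && is.finite(crossover_pct))
    graphics::abline(v = crossover_pct, lwd = 2)
  graphics::box()
}

# first normalized-time % at which the two thigh angle traces cross
thigh_crossover_pct <- function(step) {
  sfx <- function(side) if (side == "left") "L" else "R"
  d <- step$angles[, paste0("thigh_", sfx(step$trailing_side))] -
    step$angles[, paste0("thigh_", sfx(step$leading_side))]
  sgn <- sign(d)
  i <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(i)) return(NA_real_)
  100 * (i[1] - 1) / (length(d) - 1)
}

#' Plot an individual coordination profile
#'
#' Bar height is segment dominancy (50-100%), bar colour the coordination bin;
#' the grey area shades stance (from touchdown onward). For the thigh-thigh
#' coupling a vertical line can mark the thigh crossover.
#'
#' @param profile a `coordination_profile`.
#' @param out output file path (`.png` or `.svg`).
#' @param crossover_pct optional crossover position in normalized time %.
#' @return invisibly, `out`.
#' @export
plot_profile <- function(profile, out, crossover_pct = NULL) {
  stopifnot(inherits(profile, "coordination_profile"))
  iv <- profile$intervals
  if (!any(iv$defined))
    stop("plot_profile: profile has no defined intervals", call. = FALSE)
  open_device(out)
  on.exit(grDevices::dev.off())
  draw_profile_panel(iv$pct, iv$dominancy, iv$color, profile$touchdown_pct,
                     main = sprintf("%s, step %d, %s", profile$participant_id,
                                    profile$step_index, profile$coupling),
                     crossover_pct = crossover_pct)
  invisible(out)
}

#' Plot a group coordination profile with its SD curve
#'
#' Top panel: mean-profile bars coloured by the circular-mean bin; bottom
#' panel: between-individual circular SD.
#'
#' @param gp a `group_profile` from [group_profile()].
#' @param out output file path (`.png` or `.svg`).
#' @return invisibly, `out`.
#' @export
plot_group_profile <- function(gp, out) {
  stopifnot(inherits(gp, "group_profile"))
  dict <- bin_dictionary(attr(gp, "coupling"))
  open_device(out, height = 6.5)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  col <- ifelse(is.na(gp$mean_bin), NA_character_,
                dict$color[gp$mean_bin + 1L])
  draw_profile_panel(gp$pct, gp$mean_dominancy, col,
                     attr(gp, "mean_touchdown_pct"),
                     main = sprintf("group mean, step %s, %s",
                                    paste(attr(gp, "step_index"),
                                          collapse = "/"),
                                    attr(gp, "coupling")))
  graphics::plot(gp$pct, gp$sd_deg, type = "l", lwd = 2, xaxs = "i",
                 xlim = c(0, 100), ylim = c(0, max(gp$sd_deg, 10,
                                                   na.rm = TRUE) * 1.05),
                 xlab = "normalized time (%)", ylab = "circular SD (deg)",
                 main = "between-individual variation")
  invisible(out)
}

#' Plot between-individual SD curves for several steps
#'
#' @param gps named list of `group_profile`s (one per step).
#' @param out output file path.
#' @return invisibly, `out`.
#' @export
plot_sd_curves <- function(gps, out) {
  open_device(out)
  on.exit(grDevices::dev.off())
  ylim <- c(0, max(vapply(gps, function(g) max(g$sd_deg, na.rm = TRUE),
                          numeric(1))) * 1.05)
  graphics::plot(NULL, xlim = c(0, 100), ylim = ylim, xaxs = "i",
                 xlab = "normalized time (%)", ylab = "circular SD (deg)",
                 main = "between-individual variation by step")
  for (i in seq_along(gps))
    graphics::lines(gps[[i]]$pct, gps[[i]]$sd_deg, lwd = 2, lty = i)
  graphics::legend("topright", legend = names(gps), lty = seq_along(gps),
                   lwd = 2, bty = "n")
  invisible(out)
}

#' Plot a bin-frequency heat table
#'
#' Mean bin frequency (%) per step, bins on the y axis in their dictionary
#' colours, matching the bin-frequency matrices of coordination-profile
#' figures.
#'
#' @param freq_table long table from [bin_frequency_table()] (one coupling).
#' @param out output file path.
#' @return invisibly, `out`.
#' @export
plot_bin_frequencies <- function(freq_table, out) {
  cp <- unique(freq_table$coupling)
  if (length(cp) != 1L)
    stop("plot_bin_frequencies: one coupling at a time", call. = FALSE)
  dict <- bin_dictionary(cp)
  agg <- stats::aggregate(freq_pct ~ step + bin, freq_table, mean)
  steps <- sort(unique(agg$step))
  open_device(out, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  graphics::plot(NULL, xlim = c(0.5, length(steps) + 0.5), ylim = c(-0.5, 7.5),
                 xlab = "step", ylab = "", axes = FALSE,
                 main = sprintf("mean bin frequencies: %s", cp))
  graphics::axis(1, at = seq_along(steps), labels = steps)
  graphics::axis(2, at = 0:7, labels = dict$label, las = 1, cex.axis = 0.8)
  for (i in seq_len(nrow(agg))) {
    xs <- match(agg$step[i], steps)
    shade <- grDevices::adjustcolor(dict$color[agg$bin[i] + 1L],
                                    alpha.f = min(1, agg$freq_pct[i] / 100 + 0.08))
    graphics::rect(xs - 0.5, agg$bin[i] - 0.5, xs + 0.5, agg$bin[i] + 0.5,
                   col = shade, border = "white")
    graphics::text(xs, agg$bin[i], sprintf("%.0f", agg$freq_pct[i]),
                   cex = 0.8)
  }
  invisible(out)
}
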