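# Discrete kinematics extraction and the inferential layer: one-way
# repeated-measures ANOVA with Mauchly/Greenhouse-Geisser sphericity handling,
# Friedman tests, Wilcoxon signed-rank tests, Bonferroni adjustment.

#' Segment angles at touchdown and toe-off
#'
#' Interpolates the (filtered) raw angle series at each step's touchdown and
#' closing toe-off instants. The thigh/shank/foot variables refer to the limb
#' that is in stance during the step (the leading limb, which touches down
#' within it).
#'
#' @param trial a [sprint_trial()].
#' @param n_steps number of steps (default all available).
#' @param config an [analysis_config()] (filtering).
#' @return `data.frame` with `participant`, `step`, `event`
#'   (`"touchdown"`/`"toe_off"`), `variable` (`trunk`, `thigh`, `shank`,
#'   `foot`), `angle_deg`.
#' @export
extract_event_angles <- function(trial, n_steps = NULL,
                                 config = analysis_config()) {
  filtered <- filter_trial(trial, config)
  windows <- segment_steps(filtered, n_steps)
  sfx <- function(side) if (side == "left") "L" else "R"
  at_time <- function(seg, t) {
    s <- filtered$series[[seg]]
    sp <- series_span(s)
    if (t < sp[1] - 1e-9 || t > sp[2] + 1e-9)
      stop(sprintf("extract_event_angles: event at %.3f s outside %s span", t,
                   seg), call. = FALSE)
    stats::approx(series_times(s), s$values, xout = t, rule = 2)$y
  }
  rows <- list()
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    segs <- c(trunk = "trunk",
              thigh = paste0("thigh_", sfx(w$leading_side)),
              shank = paste0("shank_", sfx(w$leading_side)),
              foot = paste0("foot_", sfx(w$leading_side)))
    for (ev in c("touchdown", "toe_off")) {
      t <- if (ev == "touchdown") w$t_td else w$t_end
      rows[[length(rows) + 1L]] <- data.frame(
        participant = trial$participant_id, step = w$step_index, event = ev,
        variable = names(segs), angle_deg = vapply(segs, at_time, numeric(1),
                                                   t = t),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

# orthonormal contrasts spanning the space orthogonal to the intercept
orthonormal_contrasts <- function(k) {
  M <- stats::contr.helmert(k)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' One-way repeated-measures ANOVA
#'
#' Tests a within-subject (step) effect on a complete participants x steps
#' matrix. Sphericity is assessed with Mauchly's test; when violated
#' (Mauchly p < `alpha`), Greenhouse-Geisser epsilon corrects the degrees of
#' freedom and p-value. The reported effect size is partial eta squared,
#' SS_effect / (SS_effect + SS_error).
#'
#' @param values numeric matrix, participants in rows, steps in columns
#'   (>= 3 rows, >= 2 columns, no missing cells).
#' @param alpha Mauchly significance threshold for applying the correction
#'   (default 0.05).
#' @return object of class `rm_anova`: list with `F`, `df_num`, `df_den`, `p`,
#'   `eta_sq`, `gg_applied`, `epsilon`, `mauchly_w`, `mauchly_p`,
#'   `df_num_uncorrected`, `df_den_uncorrected`.
#' @export
rm_anova <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (anyNA(values))
    stop("rm_anova: matrix must be complete (listwise completeness required)",
         call. = FALSE)
  if (n < 3L || k < 2L)
    stop("rm_anova: need >= 3 participants and >= 2 steps", call. = FALSE)
  grand <- mean(values)
  row_m <- rowMeans(values); col_m <- colMeans(values)
  ss_effect <- n * sum((col_m - grand)^2)
  ss_subject <- k * sum((row_m - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_error <- ss_total - ss_effect - ss_subject
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  ms_effect <- ss_effect / df1
  ms_error <- ss_error / df2
  F <- if (ms_error <= 0) 0 else ms_effect / ms_error
  eta_sq <- if (ss_effect + ss_error <= 0) 0 else
    ss_effect / (ss_effect + ss_error)

  # sphericity on the orthonormal-contrast covariance
  M <- orthonormal_contrasts(k)
  Sc <- stats::cov(values %*% M)
  d <- k - 1L
  eigs <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(eigs)
  epsilon <- if (tr <= 0) 1 else tr^2 / (d * sum(eigs^2))
  epsilon <- min(1, max(epsilon, 1 / d))
  if (d >= 2L && all(eigs > 0)) {
    W <- prod(eigs) / (tr / d)^d
    cfac <- (n - 1) - (2 * d^2 + d + 2) / (6 * d)
    chi <- -cfac * log(W)
    mdf <- d * (d + 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi, mdf, lower.tail = FALSE)
    mauchly_w <- W
  } else {
    mauchly_w <- NA_real_; mauchly_p <- NA_real_  # k = 2: sphericity trivial
  }
  gg_applied <- !is.na(mauchly_p) && mauchly_p < alpha
  adf1 <- if (gg_applied) epsilon * df1 else df1
  adf2 <- if (gg_applied) epsilon * df2 else df2
  p <- stats::pf(F, adf1, adf2, lower.tail = FALSE)
  structure(
    list(F = F, df_num = adf1, df_den = adf2, p = p, eta_sq = eta_sq,
         gg_applied = gg_applied, epsilon = epsilon,
         mauchly_w = mauchly_w, mauchly_p = mauchly_p,
         df_num_uncorrected = df1, df_den_uncorrected = df2),
    class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("F(%.4g, %.4g) = %.3f, p = %.4g, partial eta^2 = %.3f%s\n",
              x$df_num, x$df_den, x$F, x$p, x$eta_sq,
              if (x$gg_applied)
                sprintf(" [Greenhouse-Geisser, epsilon = %.3f]", x$epsilon)
              else ""))
  invisible(x)
}

# mid-ranks per row
row_midranks <- function(values) t(apply(values, 1L, rank))

friedman_statistic <- function(R) {
  n <- nrow(R); k <- ncol(R)
  colsum <- colSums(R)
  num <- (k - 1) * sum((colsum - n * (k + 1) / 2)^2)
  den <- sum(R^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)  # all rows fully tied
  num / den
}

#' Friedman rank test across steps
#'
#' Tie-robust Friedman chi-squared on a complete participants x steps matrix,
#' using mid-ranks within participants. For small samples an exact permutation
#' p-value (full enumeration of within-row rank permutations) is available.
#'
#' @param values numeric matrix, participants in rows, steps in columns.
#' @param exact compute the exact permutation p-value (only allowed when
#'   `factorial(k)^n <= max_enum`).
#' @param max_enum enumeration budget for `exact = TRUE` (default 1e6).
#' @return list with `chi_sq`, `df`, `p` (asymptotic) and, when requested,
#'   `p_exact`.
#' @export
friedman <- function(values, exact = FALSE, max_enum = 1e6) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop("friedman: matrix must be complete", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (k < 2L)
    stop("friedman: need >= 2 steps", call. = FALSE)
  R <- row_midranks(values)
  chi <- friedman_statistic(R)
  df <- k - 1L
  out <- list(chi_sq = chi, df = df,
              p = stats::pchisq(chi, df, lower.tail = FALSE))
  if (exact) {
    n_arr <- factorial(k)^n
    if (n_arr > max_enum)
      stop(sprintf("friedman: exact enumeration infeasible (%g arrangements)",
                   n_arr), call. = FALSE)
    perms <- permutations_of(k)
    stats_all <- enumerate_friedman(R, perms)
    out$p_exact <- mean(stats_all >= chi - 1e-12)
  }
  out
}

# all permutations of 1..k as a matrix (k! rows)
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                   sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# full enumeration of the Friedman statistic under within-row permutations
enumerate_friedman <- function(R, perms) {
  n <- nrow(R); k <- ncol(R); m <- nrow(perms)
  idx <- rep(1L, n)
  total <- m^n
  stats_all <- numeric(total)
  Rp <- R
  for (t in seq_len(total)) {
    for (i in seq_len(n)) Rp[i, ] <- R[i, perms[idx[i], ]]
    stats_all[t] <- friedman_statistic(Rp)
    # odometer increment
    i <- 1L
    while (i <= n) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= m) break
      idx[i] <- 1L; i <- i + 1L
    }
  }
  stats_all
}

# exact null distribution of the signed-rank statistic: number of sign
# assignments of ranks 1..n summing to each value 0..n(n+1)/2
signrank_counts <- function(n) {
  maxw <- n * (n + 1) / 2
  counts <- c(1, numeric(maxw))  # counts[w + 1] = #subsets of {1..n} with sum w
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), counts[seq_len(maxw + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are mid-ranked. The
#' statistic `W` is the sum of ranks of positive differences. The p-value is
#' exact (full enumeration of sign assignments) for n <= 25 without ties in
#' the absolute differences, otherwise a normal approximation with continuity
#' and tie corrections is used.
#'
#' @param a,b paired numeric vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   `NULL` (default) decides automatically.
#' @return list with `W`, `n` (non-zero pairs), `p` (two-sided), `exact`
#'   (logical), `degenerate` (`TRUE` when all differences were zero, p = 1).
#' @export
wilcoxon_signed_rank <- function(a, b, exact = NULL) {
  if (length(a) != length(b))
    stop("wilcoxon_signed_rank: inputs must be paired", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(W = NA_real_, n = 0L, p = 1, exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (is.null(exact)) exact <- n <= 25L && !ties
  if (exact && ties)
    stop("wilcoxon_signed_rank: exact p undefined with tied ranks",
         call. = FALSE)
  if (exact) {
    counts <- signrank_counts(n)
    total <- 2^n
    pless <- sum(counts[seq_len(W + 1)]) / total
    pgreater <- sum(counts[seq(W + 1, length(counts))]) / total
    p <- min(1, 2 * min(pless, pgreater))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(W = W, n = n, p = p, exact = exact, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param m number of comparisons (default `length(p_values)`).
#' @return adjusted p-values, `pmin(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("bonferroni: p-values must be in [0, 1]", call. = FALSE)
  pmin(1, p_values * m)
}

#' Pairwise step comparisons with Bonferroni adjustment
#'
#' All pairwise comparisons between columns (steps) of a participants x steps
#' matrix, via paired t-tests or Wilcoxon signed-rank tests, Bonferroni
#' adjusted over the number of pairs.
#'
#' @param values numeric matrix, participants in rows, steps in columns.
#' @param method `"t"` or `"wilcoxon"`.
#' @return `data.frame` with `step_a`, `step_b`, `statistic`, `p_raw`,
#'   `p_adjusted`.
#' @export
pairwise_steps <- function(values, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  k <- ncol(values)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (method == "t") {
      tt <- stats::t.test(values[, i1], values[, i2], paired = TRUE)
      data.frame(step_a = i1, step_b = i2,
                 statistic = unname(tt$statistic), p_raw = tt$p.value)
    } else {
      w <- wilcoxon_signed_rank(values[, i1], values[, i2])
      data.frame(step_a = i1, step_b = i2, statistic = w$W, p_raw = w$p)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, m)
  out
}

#' Step-effect report for discrete kinematics
#'
#' For each variable x event combination, runs [rm_anova()] across steps and
#' Bonferroni-adjusted pairwise t-tests, formatted like a discrete-kinematics
#' results table (mean ± SD per step, F, p, partial eta squared).
#'
#' @param kinematics long table from [extract_event_angles()] pooled over
#'   participants.
#' @return list with `anova` (one row per variable x event) and `pairwise`.
#' @export
kinematics_report <- function(kinematics) {
  combos <- unique(kinematics[, c("variable", "event")])
  anova_rows <- list(); pw_rows <- list()
  for (i in seq_len(nrow(combos))) {
    v <- combos$variable[i]; e <- combos$event[i]
    sub <- kinematics[kinematics$variable == v & kinematics$event == e, ]
    wide <- stats::reshape(sub[, c("participant", "step", "angle_deg")],
                           idvar = "participant", timevar = "step",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    if (anyNA(mat))
      stop(sprintf("kinematics_report: incomplete data for %s at %s", v, e),
           call. = FALSE)
    res <- rm_anova(mat)
    msd <- sprintf("%.1f±%.1f", colMeans(mat), apply(mat, 2, stats::sd))
    anova_rows[[i]] <- data.frame(
      variable = v, event = e,
      t(setNames(msd, paste0("step", seq_len(ncol(mat))))),
      F = res$F, df_num = res$df_num, df_den = res$df_den, p = res$p,
      eta_sq = res$eta_sq, gg_applied = res$gg_applied,
      stringsAsFactors = FALSE)
    pw <- pairwise_steps(mat, "t")
    pw$variable <- v; pw$event <- e
    pw_rows[[i]] <- pw
  }
  list(anova = do.call(rbind, anova_rows),
       pairwise = do.call(rbind, pw_rows))
}

#' Friedman + Wilcoxon report for bin frequencies
#'
#' For each coupling x bin, compares bin frequencies across steps with a
#' Friedman test and Bonferroni-adjusted pairwise Wilcoxon signed-rank tests.
#' Bins with zero frequency for all participants in all steps are skipped
#' (test undefined) and listed in `skipped`.
#'
#' @param freq_table long table from [bin_frequency_table()].
#' @return list with `friedman` (per coupling x bin), `pairwise`, `skipped`.
#' @export
bin_frequency_report <- function(freq_table) {
  fr_rows <- list(); pw_rows <- list(); skipped <- list()
  for (cp in unique(freq_table$coupling)) {
    sub_c <- freq_table[freq_table$coupling == cp, ]
    for (b in sort(unique(sub_c$bin))) {
      sub <- sub_c[sub_c$bin == b, ]
      wide <- stats::reshape(sub[, c("participant", "step", "freq_pct")],
                             idvar = "participant", timevar = "step",
                             direction = "wide")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      if (all(mat == 0)) {
        skipped[[length(skipped) + 1L]] <- data.frame(coupling = cp, bin = b)
        next
      }
      fr <- friedman(mat)
      fr_rows[[length(fr_rows) + 1L]] <- data.frame(
        coupling = cp, bin = b, chi_sq = fr$chi_sq, df = fr$df, p = fr$p,
        stringsAsFactors = FALSE)
      pw <- pairwise_steps(mat, "wilcoxon")
      pw$coupling <- cp; pw$bin <- b
      pw_rows[[length(pw_rows) + 1L]] <- pw
    }
  }
  list(friedman = do.call(rbind, fr_rows),
       pairwise = do.call(rbind, pw_rows),
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
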