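test_that("extract_event_angles interpolates at event instants", {
  # trunk ramps 0 -> 10 deg over [0, 1]; TD_1 at 0.32 s -> 3.2 deg
  tr <- fixture_trial(fns = list(trunk = function(t) 10 * t))
  kin <- extract_event_angles(tr, config = analysis_config(lowpass_cutoff = NA))
  expect_setequal(unique(kin$variable), c("trunk", "thigh", "shank", "foot"))
  td1 <- kin[kin$step == 1 & kin$event == "touchdown" &
               kin$variable == "trunk", ]
  expect_equal(td1$angle_deg, 3.2, tolerance = 1e-9)
  to1 <- kin[kin$step == 1 & kin$event == "toe_off" &
               kin$variable == "trunk", ]
  expect_equal(to1$angle_deg, 5.2, tolerance = 1e-9)
  # stance-limb mapping: step 1 leads left, step 2 leads right
  th1 <- kin[kin$step == 1 & kin$variable == "thigh", ]
  th2 <- kin[kin$step == 2 & kin$variable == "thigh", ]
  # thigh_L is segment 2 (20 + 5t), thigh_R is segment 3 (30 + 5t)
  expect_equal(th1$angle_deg[th1$event == "touchdown"], 20 + 5 * 0.32)
  expect_equal(th2$angle_deg[th2$event == "touchdown"], 30 + 5 * 0.60)
})

test_that("rm_anova matches the base R multivariate oracle", {
  set.seed(42)
  m <- matrix(rnorm(21 * 4), 21, 4) + outer(rnorm(21), rep(1, 4))
  r <- rm_anova(m)
  fit <- lm(m ~ 1)
  id <- data.frame(step = factor(1:4))
  mt <- mauchly.test(fit, M = ~step, X = ~1, idata = id)
  expect_equal(r$mauchly_w, unname(mt$statistic), tolerance = 1e-9)
  expect_equal(r$mauchly_p, mt$p.value, tolerance = 1e-3)
  a <- anova(fit, M = ~step, X = ~1, idata = id, test = "Spherical")
  expect_equal(r$F, a$F[1], tolerance = 1e-9)
  expect_equal(r$p, a$`Pr(>F)`[1], tolerance = 1e-9)
  # epsilon validated through the corrected p the oracle reports
  expect_equal(pf(r$F, r$epsilon * 3, r$epsilon * 60, lower.tail = FALSE),
               a$`G-G Pr`[1], tolerance = 1e-9)
  expect_false(r$gg_applied)
  # uncorrected dfs for a 21 x 4 design
  expect_equal(r$df_num, 3)
  expect_equal(r$df_den, 60)

  # strongly non-spherical data: correction engages, dfs shrink
  set.seed(8)
  base <- rnorm(21)
  ns <- cbind(base + rnorm(21, sd = 0.05), base + rnorm(21, sd = 0.05),
              rnorm(21, sd = 3), rnorm(21, sd = 6))
  rn <- rm_anova(ns)
  expect_true(rn$gg_applied)
  expect_lt(rn$df_num, 3)
  expect_equal(rn$df_num / 3, rn$epsilon)
  expect_gte(rn$epsilon, 1 / 3)
  an <- anova(lm(ns ~ 1), M = ~step, X = ~1, idata = id, test = "Spherical")
  expect_equal(rn$p, an$`G-G Pr`[1], tolerance = 1e-9)
})

test_that("rm_anova degenerate and identity cases", {
  # identical columns: no step effect
  m <- matrix(rep(rnorm(10), 4), 10, 4)
  r <- rm_anova(m)
  expect_equal(r$F, 0)
  expect_equal(r$eta_sq, 0)
  # 2 steps: F equals the squared paired t statistic
  set.seed(7)
  m2 <- matrix(rnorm(24), 12, 2)
  r2 <- rm_anova(m2)
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-9)
  # partial eta squared: SS_effect / (SS_effect + SS_error)
  set.seed(13)
  m3 <- matrix(rnorm(40), 10, 4) + matrix(rep(c(0, 2, 4, 6), each = 10), 10, 4)
  r3 <- rm_anova(m3)
  expect_gt(r3$eta_sq, 0.5)
  expect_lte(r3$eta_sq, 1)
  expect_error(rm_anova(m3[1:2, ]), ">= 3 participants")
  m3[2, 3] <- NA
  expect_error(rm_anova(m3), "complete")
})

test_that("friedman matches base R and its exact enumeration", {
  set.seed(1)
  m <- matrix(rnorm(21 * 4), 21, 4)
  fr <- friedman(m)
  base <- friedman.test(m)
  expect_equal(fr$chi_sq, unname(base$statistic), tolerance = 1e-12)
  expect_equal(fr$df, unname(base$parameter))
  expect_equal(fr$p, base$p.value, tolerance = 1e-12)
  # identical columns: chi-squared 0, p = 1
  same <- matrix(rep(rnorm(6), 3), 6, 3)
  fr0 <- friedman(same)
  expect_equal(fr0$chi_sq, 0)
  expect_equal(fr0$p, 1)
  # 3 x 3 strictly increasing rows: chi^2 = 6, df = 2; exact p = 6/216
  inc <- matrix(c(1, 2, 3, 2, 4, 6, 1, 5, 9), 3, 3, byrow = TRUE)
  fre <- friedman(inc, exact = TRUE)
  expect_equal(fre$chi_sq, 6)
  expect_equal(fre$df, 2)
  expect_equal(fre$p_exact, 6 / 6^3)
  # asymptotic vs exact permutation p for n = 6, k = 3: the chi-squared
  # approximation tracks the enumeration closely in the decision-relevant
  # tail (exact p <= 0.1); mid-distribution it deviates by up to ~0.13
  set.seed(33)
  m6 <- matrix(rnorm(18), 6, 3)
  fr6 <- friedman(m6, exact = TRUE)
  expect_gte(fr6$p_exact, 0)
  expect_lte(fr6$p_exact, 1)
  m_tail <- matrix(rep(c(1, 2, 3), each = 6), 6, 3) +
    matrix(rnorm(18, sd = 0.1), 6, 3)
  ft <- friedman(m_tail, exact = TRUE)
  expect_lte(ft$p_exact, 0.1)
  expect_lt(abs(ft$p - ft$p_exact), 0.02)
  # ties get mid-ranks, matching base R
  mt <- matrix(c(1, 1, 2, 3, 3, 3, 2, 5, 4), 3, 3, byrow = TRUE)
  expect_equal(friedman(mt)$chi_sq, unname(friedman.test(mt)$statistic),
               tolerance = 1e-12)
  expect_error(friedman(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("wilcoxon_signed_rank: exact enumeration, ties, degeneracy", {
  # n = 6 all-positive differences: W = 21, exact two-sided p = 0.03125
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(w$W, 21)
  expect_equal(w$p, 0.03125)
  expect_true(w$exact)
  # exact p matches full base R enumeration for n <= 10
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    mine <- wilcoxon_signed_rank(a, b)
    base <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$W, unname(base$statistic))
    expect_equal(mine$p, base$p.value, tolerance = 1e-12)
  }
  # symmetric differences: p in the non-significant region
  ws <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_gt(ws$p, 0.9)
  # all differences zero: degenerate, p = 1
  wd <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(wd$degenerate)
  expect_equal(wd$p, 1)
  # tied |differences|: falls back to the corrected normal approximation
  wt <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7, 8, 9),
                             c(1, 2, 3, 4, 5, 6, 7, 10))
  expect_false(wt$exact)
  bt <- wilcox.test(c(2, 3, 4, 5, 6, 7, 8, 9), c(1, 2, 3, 4, 5, 6, 7, 10),
                    paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(wt$p, bt$p.value, tolerance = 1e-9)
})

test_that("bonferroni caps at 1 and pairwise_steps adjusts over all pairs", {
  expect_equal(bonferroni(0.01, 6), 0.06)
  expect_equal(bonferroni(0.5, 6), 1)
  expect_equal(bonferroni(c(0.2, 0.9)), c(0.4, 1))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
  set.seed(2)
  m <- matrix(rnorm(40), 10, 4)
  pw <- pairwise_steps(m, "t")
  expect_equal(nrow(pw), 6)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 6))
  pww <- pairwise_steps(m, "wilcoxon")
  expect_equal(nrow(pww), 6)
  expect_true(all(pww$p_adjusted >= pww$p_raw))
})

test_that("reports assemble ANOVA and Friedman layers over cohort tables", {
  set.seed(99)
  cfg <- sim_config(n_participants = 6, rng_seed = 99)
  cohort <- generate_cohort(cfg)
  kin <- do.call(rbind, lapply(cohort, extract_event_angles))
  kr <- kinematics_report(kin)
  expect_equal(nrow(kr$anova), 8)   # 4 variables x 2 events
  expect_true(all(kr$anova$eta_sq >= 0 & kr$anova$eta_sq <= 1))
  expect_equal(nrow(kr$pairwise), 8 * 6)
  # trunk touchdown carries the built-in step effect
  tr_td <- kr$anova[kr$anova$variable == "trunk" &
                      kr$anova$event == "touchdown", ]
  expect_lt(tr_td$p, 0.01)

  profs <- unlist(lapply(cohort, trial_profiles, coupling = "thigh_thigh"),
                  recursive = FALSE)
  freq <- bin_frequency_table(profs)
  br <- bin_frequency_report(freq)
  expect_true(all(br$friedman$df == 3))
  expect_true(all(br$friedman$p >= 0 & br$friedman$p <= 1))
  # a bin at zero frequency for everyone in every step is skipped
  freq0 <- freq
  freq0$freq_pct[freq0$bin == 5] <- 0
  br0 <- bin_frequency_report(freq0)
  expect_true(!is.null(br0$skipped))
  expect_true(5 %in% br0$skipped$bin)
  expect_false(5 %in% br0$friedman$bin)
})
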