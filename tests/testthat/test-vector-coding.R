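test_that("coupling_angle handles axes, diagonals and ramps", {
  # axis/diagonal increment cases
  expect_equal(coupling_angle(c(0, 1), c(0, 1)), 45)
  expect_equal(coupling_angle(c(0, 0), c(0, 1)), 90)
  expect_equal(coupling_angle(c(0, -1), c(0, 0)), 180)
  expect_equal(coupling_angle(c(0, 1), c(0, -1)), 315)
  # both increments zero -> undefined
  expect_true(is.na(coupling_angle(c(1, 1), c(2, 2))))
  # linear ramps 3t and 4t -> constant atan(4/3) at every interval
  t <- seq(0, 1, length.out = 101)
  g <- coupling_angle(3 * t, 4 * t)
  expect_length(g, 100)
  expect_equal(g, rep(atan2(4, 3) * 180 / pi, 100), tolerance = 1e-9)
  expect_error(coupling_angle(1:3, 1:4), "equal length")
})

test_that("dominancy implements the gradian conversion", {
  # the paper's worked example: 90 deg CA = 100 gradians = 100% distal
  d90 <- dominancy(90)
  expect_equal(d90$dominant, "distal")
  expect_equal(d90$dominancy, 100)
  # diagonals: equal rotation, tie to distal
  d45 <- dominancy(45)
  expect_equal(d45$dominancy, 50)
  expect_equal(d45$dominant, "distal")
  # gradian arithmetic off the axes
  d <- dominancy(112.5)
  expect_equal(d$dominant, "distal")
  expect_equal(d$dominancy, 75)
  expect_equal(dominancy(30)$dominant, "proximal")
  expect_equal(dominancy(30)$dominancy, 100 - 30 * 100 / 90)
  # bounds over a dense sweep; exactly 100 on axes, 50 on diagonals
  g <- seq(0, 359.9, by = 0.1)
  dom <- dominancy(g)$dominancy
  expect_true(all(dom >= 50 & dom <= 100))
  expect_equal(dom[g %in% c(0, 90, 180, 270)], rep(100, 4))
  expect_equal(dom[g %in% c(45, 135, 225, 315)], rep(50, 4))
  expect_true(is.na(dominancy(NA_real_)$dominancy))
})

test_that("classify_bin: 8 bins, 45 deg each, partitioning [0, 360)", {
  g <- seq(0, 359.95, by = 0.05)
  bins <- classify_bin(g)
  expect_setequal(unique(bins), 0:7)
  # each bin spans 45 degrees (up to the diagonal tie rule, which moves the
  # boundary point itself between neighbouring bins)
  widths <- tapply(g, bins, function(x) diff(range(x)))
  expect_true(all(widths >= 44.8 & widths <= 45))
  # spec worked cases
  expect_equal(classify_bin(30), 0L)    # in-phase (+), proximal dominant
  expect_equal(classify_bin(100), 2L)   # anti-phase, distal (+) dominant
  expect_equal(classify_bin(350), 7L)   # anti-phase, proximal (+) dominant
  # boundary rule: diagonals go to the distal-dominant bin by default
  expect_equal(classify_bin(c(45, 135, 225, 315)), c(1L, 2L, 5L, 6L))
  expect_equal(classify_bin(c(45, 135, 225, 315), rule = "lower"),
               c(1L, 3L, 5L, 7L))
  # the two rules agree away from diagonals
  off <- g[abs(g %% 90 - 45) > 0.01]
  expect_identical(classify_bin(off), classify_bin(off, rule = "lower"))
  expect_true(is.na(classify_bin(NA_real_)))
})

test_that("bin labels and colours follow the coupling's naming convention", {
  d <- bin_dictionary("thigh_thigh")
  expect_equal(nrow(d), 8)
  expect_equal(d$label[8], "anti-phase trailing (+)")
  expect_equal(d$label[3], "anti-phase leading (+)")
  expect_equal(d$label[4], "anti-phase trailing (-)")
  expect_equal(d$label[7], "anti-phase leading (-)")
  expect_true(all(grepl("in-phase", d$label[c(1, 2, 5, 6)])))
  ds <- bin_dictionary("shank_foot")
  expect_equal(ds$label[3], "anti-phase foot (+)")
  expect_equal(ds$label[7], "anti-phase foot (-)")
  expect_error(bin_dictionary("hip_knee"), "unknown coupling")
})

test_that("oracle equivalence: gamma-based bins match the sign/magnitude classifier", {
  set.seed(2024)
  n <- 1e5
  dp <- rnorm(n)
  dd <- rnorm(n)
  # away from exact boundaries (measure-zero under continuous draws, but be
  # explicit): drop near-ties and near-axes
  keep <- abs(abs(dd) - abs(dp)) > 1e-9 & abs(dp) > 1e-12 & abs(dd) > 1e-12
  dp <- dp[keep]; dd <- dd[keep]
  gamma <- coupling_angle(cumsum(c(0, dp)), cumsum(c(0, dd)))
  expect_identical(classify_bin(gamma), oracle_bins_from_increments(dp, dd))
})

test_that("swapping proximal and distal swaps dominant labels, keeps phase", {
  set.seed(11)
  p <- cumsum(rnorm(200)); d <- cumsum(rnorm(200))
  g1 <- coupling_angle(p, d)
  g2 <- coupling_angle(d, p)
  b1 <- bin_dictionary("generic")[classify_bin(g1) + 1L, ]
  b2 <- bin_dictionary("generic")[classify_bin(g2) + 1L, ]
  expect_identical(b1$phase, b2$phase)
  off_diag <- abs(g1 %% 90 - 45) > 1e-6
  expect_identical(b1$dominant[off_diag],
                   ifelse(b2$dominant[off_diag] == "proximal",
                          "distal", "proximal"))
  dom1 <- dominancy(g1); dom2 <- dominancy(g2)
  expect_equal(dom1$dominancy[off_diag], dom2$dominancy[off_diag],
               tolerance = 1e-9)
})

test_that("build_profile composes the pipeline per interval", {
  # anti-phase synthetic thighs: trailing increment = +2, leading = -1
  # (trailing = proximal); gamma = atan2(-1, 2) mod 360, constant
  n <- 101
  trail <- seq(0, 200, length.out = n)   # right side trails (step 1)
  lead <- seq(0, -100, length.out = n)
  step <- fixture_step(list(thigh_R = trail, thigh_L = lead))
  prof <- build_profile(step, "thigh_thigh")
  expect_equal(nrow(prof$intervals), 100)
  expect_equal(unname(prof$segments),
               c("thigh_R", "thigh_L")[c(1, 2)])
  g_true <- (atan2(-1, 2) * 180 / pi) %% 360
  expect_equal(prof$intervals$gamma, rep(g_true, 100), tolerance = 1e-9)
  expect_true(all(prof$intervals$bin_label == "anti-phase trailing (+)"))
  dom_true <- 100 - atan(1 / 2) * 180 / pi * 100 / 90
  expect_equal(prof$intervals$dominancy, rep(dom_true, 100),
               tolerance = 1e-9)
  expect_equal(round(dom_true, 1), 70.5)

  # both segments constant -> all undefined, nothing inherited
  step0 <- fixture_step(list(thigh_R = rep(1, n), thigh_L = rep(2, n)))
  prof0 <- build_profile(step0, "thigh_thigh")
  expect_true(all(!prof0$intervals$defined))
  expect_true(all(is.na(prof0$intervals$bin)))

  # undefined intervals inherit the previous defined bin
  mixed <- c(seq(0, 10, length.out = 51), rep(10, 25), seq(10, 5, length.out = 25))
  step_m <- fixture_step(list(thigh_R = mixed, thigh_L = mixed * 0.5))
  prof_m <- build_profile(step_m, "thigh_thigh")
  undef <- !prof_m$intervals$defined
  expect_true(any(undef))
  expect_true(all(prof_m$intervals$inherited[undef][-1] |
                    !is.na(prof_m$intervals$bin[undef][-1])))
  expect_equal(unique(prof_m$intervals$bin[prof_m$intervals$inherited]),
               prof_m$intervals$bin[max(which(prof_m$intervals$defined &
                                                seq_len(100) < 52))])
})

test_that("intra-limb couplings use the stance (leading) limb", {
  ramp <- seq(0, 10, length.out = 101)
  step <- fixture_step(list(trunk = ramp, shank_L = ramp * 2,
                            shank_R = -ramp, foot_L = ramp * 3),
                       leading_side = "left")
  pts <- build_profile(step, "trunk_shank")
  expect_equal(unname(pts$segments), c("trunk", "shank_L"))
  psf <- build_profile(step, "shank_foot")
  expect_equal(unname(psf$segments), c("shank_L", "foot_L"))
  step_r <- fixture_step(list(trunk = ramp, shank_R = ramp * 2),
                         leading_side = "right")
  expect_equal(unname(build_profile(step_r, "trunk_shank")$segments),
               c("trunk", "shank_R"))
})
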