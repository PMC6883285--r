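test_that("noiseless exponentials recover efficiency and Cq in closed form", {
  # F_c = 0.001 * 2^c crosses 0.1 where 2^c = 100
  cu <- exp_curve(2, 0.001)
  win <- window_of_linearity(cu)
  est <- reaction_efficiency_and_cq(cu, win, threshold = 0.1)
  expect_equal(est$efficiency, 2, tolerance = 1e-12)
  expect_equal(est$cq_regression, log2(100), tolerance = 1e-9)
  expect_equal(est$cq_threshold, log2(100), tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)

  for (E in c(1.7, 1.8, 1.9, 2.0)) {
    cu <- exp_curve(E, 1e-6)
    est <- reaction_efficiency_and_cq(cu, window_of_linearity(cu))
    expect_equal(est$efficiency, E, tolerance = 1e-12)
    # regression and fixed-threshold Cq agree on noiseless data
    expect_lt(abs(est$cq_regression - est$cq_threshold), 0.05)
    expect_equal(est$cq_threshold, log(0.1 / 1e-6) / log(E), tolerance = 1e-9)
  }
})

test_that("estimates converge to the closed form as fluorescence noise vanishes", {
  true_cq <- log(0.1 / 1e-6) / log(1.9)
  err <- vapply(c(1e-3, 1e-5, 1e-8), function(s) {
    set.seed(91)
    f <- 1e-6 * 1.9^(1:40) + stats::rnorm(40, 0, s)
    f[f <= 0] <- 1e-12
    cu <- amplification_curve("w", "t", "s", f)
    est <- reaction_efficiency_and_cq(cu, window_of_linearity(cu))
    abs(est$efficiency - 1.9) + abs(est$cq_threshold - true_cq)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-5)
})

test_that("baseline correction subtracts the early-cycle mean and flags flat curves", {
  f <- 0.05 + 0.001 * 2^(1:40)
  cu <- amplification_curve("w", "t", "s", f)
  cc <- correct_baseline(cu, baseline_cycles = 3:15)
  expect_equal(cc$baseline, mean(f[3:15]))
  # late cycles dominated by the exponential: corrected ~ 0.001 * 2^c
  expect_equal(cc$fluorescence[40], 0.001 * 2^40, tolerance = 1e-6)
  expect_false(cc$non_amplifying)

  # tiny template: baseline estimate is essentially the true constant
  f2 <- 0.05 + 1e-8 * 1.9^(1:40)
  cc2 <- correct_baseline(amplification_curve("w", "t", "s", f2))
  expect_equal(cc2$baseline, 0.05, tolerance = 1e-3)
  est <- reaction_efficiency_and_cq(cc2, window_of_linearity(cc2))
  expect_equal(est$efficiency, 1.9, tolerance = 1e-3)

  flat <- amplification_curve("w", "t", "s", rep(0.05, 40))
  ccf <- correct_baseline(flat)
  expect_true(ccf$non_amplifying)
  estf <- reaction_efficiency_and_cq(ccf, window = c(NA, NA))
  expect_true(estf$flags[["failed"]])
  expect_true(is.na(estf$efficiency))
})

test_that("zero-baseline exponential is unchanged by correction at late cycles", {
  f <- 1e-7 * 1.8^(1:40)
  cc <- correct_baseline(amplification_curve("w", "t", "s", f))
  # the subtracted constant is bounded by the early-cycle exponential level
  expect_lt(cc$baseline, f[16])
  expect_equal(cc$fluorescence[35] / f[35], 1, tolerance = 1e-5)
})

test_that("the window of linearity matches a brute-force scan and avoids plateau and spikes", {
  # enumerates the documented selection rule: positive, strictly increasing,
  # below 90% of the maximum, maximal R^2, ties toward earlier cycles
  brute <- function(f, points = 4) {
    best <- NULL; best_r2 <- -Inf
    for (s in seq_len(length(f) - points + 1)) {
      idx <- s:(s + points - 1)
      if (any(f[idx] <= 1e-12) || any(diff(f[idx]) <= 0) ||
          any(f[idx] > 0.9 * max(f))) next
      r2 <- stats::cor(idx, log10(f[idx]))^2
      if (r2 > best_r2 + 1e-12) { best_r2 <- r2; best <- c(s, s + points - 1) }
    }
    as.integer(best)
  }
  # exponential phase cycles 5..25, then a hard plateau
  set.seed(7)
  f <- c(rep(1e-12, 4), 1e-4 * 1.9^(1:21))
  f <- c(f, rep(f[25], 15))
  f <- f * (1 + c(rep(0, 4), stats::rnorm(21, 0, 1e-4), rep(0, 15)))
  cu <- amplification_curve("w", "t", "s", f)
  win <- window_of_linearity(cu)
  expect_identical(win, brute(f))
  expect_true(win[1] >= 5 && win[2] <= 25)

  # spiked cycle is excluded
  fs <- 1e-9 * 2^(1:40)
  fs[1:16] <- -0.001            # unusable early cycles
  fs[20] <- fs[20] * 3          # spike
  cus <- amplification_curve("w", "t", "s", fs)
  wins <- window_of_linearity(cus)
  expect_identical(wins, brute(fs))
  expect_false(20 %in% wins[1]:wins[2])

  # noiseless exponential: every window is perfect, the earliest is returned
  cue <- exp_curve(1.8, 1e-6)
  expect_identical(window_of_linearity(cue), c(1L, 4L))
  expect_error(window_of_linearity(amplification_curve("w", "t", "s",
                                                       c(1:3, rep(-1, 9)))),
               "fewer than")
})

test_that("residual baseline left in the signal biases efficiency downward monotonically", {
  f <- 1e-7 * 1.9^(1:40)
  ests <- vapply(c(0, 1e-5, 1e-4, 1e-3), function(delta) {
    cu <- amplification_curve("w", "t", "s", f + delta)
    reaction_efficiency_and_cq(cu, window = c(20L, 23L))$efficiency
  }, numeric(1))
  expect_equal(ests[1], 1.9, tolerance = 1e-12)
  expect_true(all(diff(ests) < 0))
})

test_that("per-amplicon summaries honor the plateau and outlier policies", {
  base <- data.frame(well = paste0("w", 1:3), target = "g1", sample = "s",
                     efficiency = c(1.9, 1.9, 1.9), r_squared = 0.999,
                     cq_regression = 20, cq_threshold = 20,
                     window_start = 10, window_end = 13,
                     failed = FALSE, no_plateau = FALSE, below_r2 = FALSE,
                     no_threshold_cross = FALSE, non_amplifying = FALSE)
  expect_equal(amplicon_efficiency_summary(base)$mean_efficiency, 1.9)

  flagged <- base
  flagged$efficiency[3] <- 1.5
  flagged$no_plateau[3] <- TRUE
  s <- amplicon_efficiency_summary(flagged)
  expect_equal(s$mean_efficiency, 1.9)
  expect_identical(s$n_excluded, 1L)
  expect_identical(s$n_reactions, 2L)

  out <- base[rep(1, 6), ]
  out$well <- paste0("w", 1:6)
  out$efficiency <- c(1.80, 1.81, 1.82, 1.83, 1.84, 2.40)
  incl <- amplicon_efficiency_summary(out, include_outliers = TRUE)
  excl <- amplicon_efficiency_summary(out, include_outliers = FALSE)
  expect_equal(incl$mean_efficiency, mean(out$efficiency))
  expect_equal(excl$mean_efficiency, mean(out$efficiency[-6]))
  expect_identical(excl$n_outliers, 1L)
  # identical policies when no outlier present
  expect_equal(amplicon_efficiency_summary(base, include_outliers = FALSE),
               amplicon_efficiency_summary(base, include_outliers = TRUE))

  allflag <- base
  allflag$failed <- TRUE
  expect_error(suppressWarnings(amplicon_efficiency_summary(allflag)),
               "all reactions excluded")
})

test_that("efficiency comparisons across factor levels match the ANOVA closed form", {
  mk <- function(e, day) {
    data.frame(target = "g1", efficiency = e, day = day)
  }
  # identical efficiency lists per level: between-group SS is zero
  same <- mk(c(1.8, 1.9, 1.8, 1.9), c("d1", "d1", "d2", "d2"))
  expect_equal(compare_efficiency_by_factor(same, "day")$F, 0)

  # hand-computed one-way ANOVA
  e1 <- c(1.80, 1.82, 1.84); e2 <- c(1.90, 1.92, 1.94)
  hand <- mk(c(e1, e2), rep(c("d1", "d2"), each = 3))
  gm <- mean(c(e1, e2))
  ssb <- 3 * (mean(e1) - gm)^2 + 3 * (mean(e2) - gm)^2
  ssw <- sum((e1 - mean(e1))^2) + sum((e2 - mean(e2))^2)
  f_expect <- (ssb / 1) / (ssw / 4)
  res <- compare_efficiency_by_factor(hand, "day")
  expect_equal(res$F, f_expect, tolerance = 1e-10)
  expect_identical(c(res$df1, res$df2), c(1L, 4L))

  # degenerate: no variance at all
  dg <- mk(rep(1.8, 4), c("d1", "d1", "d2", "d2"))
  resd <- compare_efficiency_by_factor(dg, "day")
  expect_true(resd$degenerate)
  expect_equal(resd$p, 1)

  expect_error(compare_efficiency_by_factor(mk(c(1.8, 1.9), c("d1", "d2")), "day"),
               "at least 2 levels")
})

test_that("the factor comparison holds its size under the null", {
  set.seed(4242)
  rejections <- vapply(seq_len(1000), function(i) {
    df <- data.frame(target = "g1",
                     efficiency = stats::rnorm(10, 1.85, 0.02),
                     day = rep(c("d1", "d2"), each = 5))
    compare_efficiency_by_factor(df, "day")$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, 0.05 - 3 * se)
  expect_lt(rate, 0.05 + 3 * se)
})
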