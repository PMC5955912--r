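test_that("boxcar smoothing matches the direct-convolution oracle", {
  expect_equal(smooth_yaw(rep(4.2, 100)), rep(4.2, 100))  # passes DC
  imp <- numeric(100)
  imp[50] <- 1
  sm <- smooth_yaw(imp)
  expect_equal(sm, boxcar_oracle(imp))
  expect_equal(sm[48:53], rep(1 / 6, 6))  # six consecutive samples of 1/6
  expect_true(all(sm[-(48:53)] == 0))
  set.seed(12)
  y <- rnorm(500)
  expect_equal(smooth_yaw(y), boxcar_oracle(y))
  expect_error(smooth_yaw(rnorm(4)), "shorter")
})

test_that("smoothing a long white-noise trace divides the variance by ~6", {
  set.seed(77)
  y <- rnorm(60000)
  ratio <- var(smooth_yaw(y)) / var(y)
  expect_equal(ratio, 1 / 6, tolerance = 0.05)
})

test_that("baseline subtraction removes the 500-ms pre-onset mean", {
  y <- rnorm(300, mean = 7)
  set.seed(2)
  out <- subtract_baseline(y, t0_index = 121)
  expect_equal(mean(out[91:120]), 0, tolerance = 1e-12)
  # constant offset removed exactly
  expect_equal(subtract_baseline(rep(3.5, 240), t0_index = 61), rep(0, 240))
  # ramp input: output crosses zero at the centroid time of the baseline
  # window (linear-algebra oracle: mean of sample times 91..120)
  ramp <- (seq_len(300) - 1) / 60
  rout <- subtract_baseline(ramp, t0_index = 121)
  centroid <- mean((91:120 - 1) / 60)
  expect_equal(rout, ramp - centroid)
  expect_error(subtract_baseline(rnorm(100), t0_index = 20), "pre-onset")
})

test_that("the OLR scalar is the half-open 1-2 s window mean (60 samples)", {
  expect_identical(olr_scalar(numeric(300), t0_index = 121), 0)
  y <- numeric(300)
  y[181:240] <- 29.5  # exactly the [t0+1, t0+2) samples
  expect_identical(olr_scalar(y, t0_index = 121), 29.5)
  # contaminating the sample just past the window must not change it
  y2 <- y
  y2[241] <- 1e6
  expect_identical(olr_scalar(y2, t0_index = 121), 29.5)
  # linear ramp a*t reads a*(t0 + 1.4917 s) (mean-of-ramp oracle)
  a <- 3.1
  ramp <- a * (seq_len(300) - 1) / 60
  expect_equal(olr_scalar(ramp, t0_index = 121), a * (2 + 1 + 59 / 120))
  expect_error(olr_scalar(numeric(200), t0_index = 121), "window")
})

test_that("preprocessing is linear: scaling commutes with smooth + baseline", {
  set.seed(31)
  y <- rnorm(300, 3)
  f <- function(v) subtract_baseline(smooth_yaw(v), t0_index = 121)
  expect_equal(f(5 * y), 5 * f(y))
  expect_equal(olr_scalar(f(5 * y), t0_index = 121),
               5 * olr_scalar(f(y), t0_index = 121))
})

test_that("direction folding implements the zero-speed-corrected average", {
  # antisymmetric case with zero-speed reference at 0: corrected = right curve
  d <- rbind(fold_df(1, 36, "right", 20), fold_df(1, 36, "left", -20),
             fold_df(1, 0, "right", 0), fold_df(1, 0, "left", 0))
  tab <- fold_olr_table(d)
  expect_identical(tab$olr, 20)
  expect_false(any(tab$speed == 0))
  # all conditions identical to the zero-speed response: all-zero output
  d2 <- rbind(fold_df(1, c(0, 0, 18, 18, 36, 36),
                      rep(c("right", "left"), 3), rep(4.4, 6)))
  expect_identical(fold_olr_table(d2)$olr, c(0, 0))
  # general oracle: ((R - Z) - (L - Z)) / 2 with a nonzero reference
  d3 <- rbind(fold_df(1, 18, "right", 10), fold_df(1, 18, "left", -6),
              fold_df(1, 0, "right", 2), fold_df(1, 0, "left", 2))
  expect_identical(fold_olr_table(d3)$olr, ((10 - 2) - (-6 - 2)) / 2)
  # contract errors
  expect_error(fold_olr_table(fold_df(1, 18, "right", 1)), "zero-speed")
  d4 <- rbind(fold_df(1, 18, "right", 1), fold_df(1, 0, "right", 0))
  expect_error(fold_olr_table(d4), "pair")
})

test_that("folding removes a common drift shared by all conditions", {
  # exactly antisymmetric responses on top of a nonzero per-mouse drift:
  # corrected OLR equals the drift-free truth
  drift <- 3.7
  d <- rbind(fold_df(2, 36, "right", 25 + drift),
             fold_df(2, 36, "left", -25 + drift),
             fold_df(2, 0, "right", drift), fold_df(2, 0, "left", drift))
  expect_equal(fold_olr_table(d)$olr, 25)
})

test_that("zero-speed corrected curves are identically zero, even with noise", {
  tr <- simulate_cohort("speed", n_mice = 2, repeats_per_session = 2,
                        n_sessions = 1, seed = 17)
  cv <- baseline_correct_curves(tr)
  z <- cv$curves[cv$info$speed == 0, , drop = FALSE]
  expect_identical(nrow(z), 2L)
  expect_true(all(z == 0))
  # and nonzero-speed curves are not flat
  nz <- cv$curves[cv$info$speed == 72, , drop = FALSE]
  expect_gt(max(abs(nz)), 1)
})

test_that("noise-free folded OLRs recover the simulated plateau", {
  quiet <- cohort_spec(noise_sd = 0, baseline_drift_sd = 0)
  tr <- simulate_cohort("speed", n_mice = 2, repeats_per_session = 1,
                        n_sessions = 1, cohort = quiet, seed = 4)
  tab <- fold_olr_table(compute_trial_olrs(tr))
  truth <- tr$mice$gain_multiplier[tab$mouse] *
    tuning_eval(tr$tuning, tab$speed)
  expect_equal(tab$olr, truth, tolerance = 1e-3)
})

test_that("across-mouse normalization equalizes mice and preserves the mean", {
  tab <- fold_df(rep(1:3, each = 4), rep(c(18, 36, 54, 72), 3), "right",
                 c(1, 2, 3, 4) * rep(c(1, 3, 0.5), each = 4))
  out <- normalize_across_mice(tab)
  # identical per-mouse mean and SD after normalization
  ms <- tapply(out$olr_norm, out$mouse, mean)
  ss <- tapply(out$olr_norm, out$mouse, sd)
  expect_equal(diff(range(ms)), 0, tolerance = 1e-12)
  expect_equal(diff(range(ss)), 0, tolerance = 1e-12)
  # pooled mean preserved
  expect_equal(mean(out$olr_norm), mean(tab$olr))
  # mice scaled versions of each other: normalized curves coincide
  expect_equal(out$olr_norm[1:4], out$olr_norm[5:8])
  expect_equal(out$olr_norm[1:4], out$olr_norm[9:12])
  # identical mice pass through unchanged
  same <- fold_df(rep(1:2, each = 3), rep(c(18, 36, 54), 2), "right",
                  rep(c(5, 9, 7), 2))
  expect_equal(normalize_across_mice(same)$olr_norm, same$olr)
  # degenerate inputs
  expect_error(normalize_across_mice(fold_df(1, c(18, 36), "right", 1:2)),
               "2 mice")
  flat <- fold_df(rep(1:2, each = 2), rep(c(18, 36), 2), "right",
                  c(1, 1, 2, 3))
  expect_error(normalize_across_mice(flat), "zero variance")
})

test_that("condition summaries use the mouse as unit of replication", {
  tab <- fold_df(rep(1:2, each = 2), rep(c(18, 36), 2), "right",
                 c(1, 5, 3, 7))
  s <- condition_summary(tab, value = "olr")
  expect_identical(s$n, c(2L, 2L))
  expect_equal(s$mean, c(2, 6))
  expect_equal(s$sem, c(1, 1))  # two mice {1,3} and {5,7}: SEM = 1
  # SEM shrinks as 1/sqrt(n) (simulation oracle)
  set.seed(6)
  sems <- vapply(c(4, 16, 64), function(n) {
    t2 <- fold_df(seq_len(n), 18, "right", rnorm(n))
    t2 <- rbind(t2, fold_df(seq_len(n), 36, "right", rnorm(n)))
    mean(condition_summary(t2, value = "olr")$sem)
  }, numeric(1))
  expect_equal(sems[1] / sems[3], sqrt(64 / 4), tolerance = 0.5)
  # identical mice: SEM 0
  same <- fold_df(1:3, 18, "right", c(2, 2, 2))
  same <- rbind(same, fold_df(1:3, 36, "right", c(4, 4, 4)))
  expect_equal(condition_summary(same, value = "olr")$sem, c(0, 0))
})

test_that("t-test against zero drives the open-marker flag", {
  expect_false(ttest_vs_zero(rep(0, 6))$significant)
  strong <- ttest_vs_zero(c(10.1, 9.9, 10.0, 10.2, 9.8, 10.0))
  expect_true(strong$significant)
  # hand computation: t = mean / (sd / sqrt(n))
  x <- c(10.1, 9.9, 10.0, 10.2, 9.8, 10.0)
  expect_equal(strong$statistic, mean(x) / (sd(x) / sqrt(6)))
  sym <- ttest_vs_zero(c(-0.1, 0.1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  expect_error(ttest_vs_zero(1), "2 mice")
})

test_that("gain is OLR over speed and undefined at rest", {
  expect_equal(compute_gain(29.5, 36.4), 0.81, tolerance = 0.005)
  expect_identical(compute_gain(0, 10), 0)
  expect_identical(compute_gain(18, 18), 1)
  expect_error(compute_gain(5, 0), "zero speed")
  tab <- add_gain(fold_df(1:2, 36, "right", c(18, 9)))
  expect_equal(tab$gain, c(0.5, 0.25))
})
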