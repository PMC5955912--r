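test_that("weighted fits match the independent normal-equation solver", {
  set.seed(101)
  for (k in 1:10) {
    n <- sample(8:20, 1)
    x <- sort(runif(n, 0, 72))
    y <- rnorm(n, 10 + 0.5 * x - 0.01 * x^2, 2)
    se <- runif(n, 0.5, 3)
    deg <- sample(1:3, 1)
    fit <- fit_poly_weighted(x, y, se, deg)
    oracle <- wls_oracle(poly_X(x, deg), y, se)
    expect_equal(unname(fit$coefficients), as.vector(oracle),
                 tolerance = 1e-8)
  }
  # surfaces too
  for (k in 1:5) {
    g <- expand.grid(x1 = c(0.1, 0.4, 0.7, 0.9), x2 = c(18, 36, 54, 72, 90))
    y <- rnorm(20, 5 + 3 * g$x1 + 0.1 * g$x2 - 0.001 * g$x2^2)
    se <- runif(20, 0.2, 2)
    fit <- fit_surface_weighted(g$x1, g$x2, y, se, c(2, 3))
    tm <- surface_terms(2, 3)
    X <- sapply(seq_len(nrow(tm)), function(j) g$x1^tm$i[j] * g$x2^tm$j[j])
    expect_equal(unname(fit$coefficients), as.vector(wls_oracle(X, y, se)),
                 tolerance = 1e-8)
  }
})

test_that("points on an exact parabola are recovered to machine precision", {
  x <- seq(9, 72, by = 9)
  y <- 2 + 0.9 * x - 0.011 * x^2
  fit <- fit_poly_weighted(x, y, se = runif(8, 0.1, 2), degree = 2)
  expect_equal(unname(fit$coefficients), c(2, 0.9, -0.011), tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  expect_equal(fit$rss_w, 0, tolerance = 1e-10)
})

test_that("with equal weights degree 1 reduces to simple linear regression", {
  set.seed(5)
  x <- 1:10
  y <- rnorm(10, 2 * x)
  fit <- fit_poly_weighted(x, y, rep(1.7, 10), 1)
  lmfit <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(lmfit)), tolerance = 1e-10)
})

test_that("up-weighting a point pulls the fit monotonically towards it", {
  set.seed(9)
  x <- 1:8
  y <- rnorm(8, x)
  res5 <- vapply(c(1, 10, 100, 1000), function(wf) {
    se <- rep(1, 8)
    se[5] <- 1 / wf
    abs(residuals(fit_poly_weighted(x, y, se, 2))[5])
  }, numeric(1))
  expect_true(all(diff(res5) < 0))
})

test_that("polyMN term rule reproduces the assay's parameter counts", {
  expect_identical(nrow(surface_terms(2, 2)), 6L)
  expect_identical(nrow(surface_terms(2, 3)), 9L)
  expect_identical(nrow(surface_terms(3, 2)), 9L)
  expect_identical(nrow(surface_terms(3, 3)), 10L)
  expect_true(all(surface_terms(2, 3)$i <= 2))
  expect_true(all(with(surface_terms(2, 3), i + j) <= 3))
})

test_that("adding terms never increases the weighted RSS", {
  set.seed(33)
  for (k in 1:8) {
    x <- seq(9, 72, by = 9)
    y <- rnorm(8, 30 - 0.01 * (x - 50)^2, 2)
    se <- runif(8, 0.5, 2)
    fits <- lapply(1:3, function(d) fit_poly_weighted(x, y, se, d))
    rss <- vapply(fits, `[[`, numeric(1), "rss_w")
    expect_true(all(diff(rss) <= 1e-10))
  }
  # and an exact poly22 truth: poly22 recovers it, poly23 cannot do worse
  g <- expand.grid(x1 = c(0.1, 0.4, 0.7, 0.9), x2 = c(18, 36, 54, 72, 90))
  tm <- surface_terms(2, 2)
  beta <- c(1, 2, 0.05, -1.5, 0.01, -0.0005)
  y22 <- as.vector(sapply(seq_len(nrow(tm)), function(j)
    g$x1^tm$i[j] * g$x2^tm$j[j]) %*% beta)
  f22 <- fit_surface_weighted(g$x1, g$x2, y22, rep(1, 20), c(2, 2))
  f23 <- fit_surface_weighted(g$x1, g$x2, y22, rep(1, 20), c(2, 3))
  expect_equal(unname(f22$coefficients), beta, tolerance = 1e-8)
  expect_lte(f23$rss_w, f22$rss_w + 1e-10)
})

test_that("nested F-tests report the assay's degree-of-freedom bookkeeping", {
  set.seed(2)
  x <- seq(9, 72, by = 9)  # 8 speeds
  y <- rnorm(8, 30 - 0.01 * (x - 50)^2, 1)
  se <- rep(1, 8)
  ft <- nested_f_test(fit_poly_weighted(x, y, se, 1),
                      fit_poly_weighted(x, y, se, 2))
  expect_identical(c(ft$df1, ft$df2), c(1L, 5L))
  g <- expand.grid(x1 = c(0.09, 0.37, 0.68, 0.89, 0.95),
                   x2 = c(18, 36, 54, 72))  # 20 condition points
  yg <- rnorm(20, 10 * g$x1 + 0.1 * g$x2)
  ft2 <- nested_f_test(fit_surface_weighted(g$x1, g$x2, yg, rep(1, 20), c(2, 2)),
                       fit_surface_weighted(g$x1, g$x2, yg, rep(1, 20), c(2, 3)))
  expect_identical(c(ft2$df1, ft2$df2), c(3L, 11L))
  ft3 <- nested_f_test(fit_surface_weighted(g$x1, g$x2, yg, rep(1, 20), c(2, 3)),
                       fit_surface_weighted(g$x1, g$x2, yg, rep(1, 20), c(3, 3)))
  expect_identical(c(ft3$df1, ft3$df2), c(1L, 10L))
  # non-nested and mismatched-data comparisons are rejected
  expect_error(nested_f_test(fit_poly_weighted(x, y, se, 2),
                             fit_poly_weighted(x, y, se, 2)), "nested")
  expect_error(nested_f_test(fit_poly_weighted(x, y, se, 1),
                             fit_poly_weighted(x, y + 1, se, 2)), "same data")
})

test_that("stepwise ladder stops at the right complexity", {
  x <- seq(9, 72, by = 9)
  # noise-free line: quadratic term brings nothing, F = 0
  sel <- select_model(x, 1 + 2 * x, rep(1, 8), c(1, 2, 3))
  expect_identical(max(sel$fit$terms$i), 1L)
  expect_false(sel$trail$accepted[1])
  expect_equal(sel$trail$F[1], 0, tolerance = 1e-9)
  # noise-free quadratic: picked exactly, cubic refused
  sel2 <- select_model(x, 30 - 0.01 * (x - 50)^2, rep(1, 8), c(1, 2, 3))
  expect_identical(max(sel2$fit$terms$i), 2L)
  # one-model ladder returns that model
  sel3 <- select_model(x, 1 + 2 * x, rep(1, 8), 2)
  expect_identical(max(sel3$fit$terms$i), 2L)
  expect_identical(nrow(sel3$trail), 0L)
})

test_that("analytic peak finding agrees with construction and flags edges", {
  # y = -(x - 57.2)^2 + 35 as an exact quadratic fit
  x <- seq(9, 72, by = 9)
  y <- 35 - (x - 57.2)^2
  pk <- peak_of_fit(fit_poly_weighted(x, y, rep(1, 8), 2), 9, 72)
  expect_equal(unname(pk$location), 57.2, tolerance = 1e-8)
  expect_equal(pk$height, 35, tolerance = 1e-8)
  expect_false(pk$boundary)
  # upward parabola: maximum on the boundary, flagged
  up <- peak_of_fit(fit_poly_weighted(x, (x - 40)^2, rep(1, 8), 2), 9, 72)
  expect_true(up$boundary)
  expect_equal(unname(up$location), 72)  # farther endpoint of the up-parabola
})

test_that("surface peaks match brute-force grid search on random surfaces", {
  set.seed(55)
  g <- expand.grid(x1 = seq(0.1, 1, length.out = 5),
                   x2 = seq(10, 80, length.out = 6))
  for (k in 1:30) {
    y <- rnorm(30, -((g$x1 - runif(1, 0.3, 0.8)) * 10)^2 -
                 ((g$x2 - runif(1, 30, 60)) / 10)^2, 0.5)
    fit <- fit_surface_weighted(g$x1, g$x2, y, rep(1, 30), c(2, 3))
    pk <- peak_of_fit(fit, c(0.1, 10), c(1, 80))
    oracle <- grid_peak_oracle(fit, c(0.1, 10), c(1, 80))
    expect_lt(abs(pk$location[1] - oracle$location[1]), 2 * oracle$step[1])
    expect_lt(abs(pk$location[2] - oracle$location[2]), 2 * oracle$step[2])
    expect_gte(pk$height, oracle$height - 1e-6)
  }
})

test_that("bootstrap peak collapses to the truth on noise-free points", {
  x <- rep(seq(9, 72, by = 9), each = 6)
  pts <- data.frame(mouse = rep(1:6, 8), speed = x,
                    olr_norm = 35 - 0.011 * (x - 57.2)^2)
  bt <- bootstrap_peak(pts, "speed", degree = 2, B = 50, seed = 3)
  expect_equal(unname(bt$mean[["speed"]]), 57.2, tolerance = 1e-6)
  expect_equal(unname(bt$sd[["speed"]]), 0, tolerance = 1e-6)
  expect_identical(nrow(bt$replicates), 50L)
})

test_that("bootstrap stores B replicates and is reproducible under a seed", {
  set.seed(71)
  x <- rep(seq(9, 72, by = 9), each = 6)
  pts <- data.frame(mouse = rep(1:6, 8), speed = x,
                    olr_norm = 35 - 0.011 * (x - 57.2)^2 + rnorm(48, 0, 1))
  b1 <- bootstrap_peak(pts, "speed", degree = 2, B = 200, seed = 10)
  b2 <- bootstrap_peak(pts, "speed", degree = 2, B = 200, seed = 10)
  expect_identical(nrow(b1$replicates), 200L)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$replicates$speed >= 9 & b1$replicates$speed <= 72))
  expect_lt(b1$ci["speed", "lower"], b1$ci["speed", "upper"])
})

test_that("2D bootstrap reports a covariance ellipse at the right scale", {
  set.seed(14)
  g <- expand.grid(mouse = 1:6, x1 = c(0.1, 0.4, 0.7, 0.9),
                   x2 = c(18, 36, 54, 72))
  g$olr_norm <- -20 * (g$x1 - 0.6)^2 - 0.01 * (g$x2 - 45)^2 + 30 +
    rnorm(nrow(g), 0, 0.5)
  bt <- bootstrap_peak(g, c("x1", "x2"), order = c(2, 3), B = 60, seed = 2)
  expect_identical(dim(bt$cov), c(2L, 2L))
  expect_identical(ncol(bt$ellipse), 2L)
  # the ellipse is centred on the bootstrap mean
  expect_equal(colMeans(bt$ellipse[-1, ]),
               unname(bt$mean[1:2]), tolerance = 0.05)
  expect_equal(unname(bt$mean[["x1"]]), 0.6, tolerance = 0.1)
  expect_equal(unname(bt$mean[["x2"]]), 45, tolerance = 5)
})
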