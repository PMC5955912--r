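# Independent oracles used across the test files. These deliberately do not
# share code with the package internals they check.

# weighted least squares by explicit normal equations, weights w = 1/se on
# the residuals (so the crossproducts carry w^2)
wls_oracle <- function(X, y, se) {
  W <- diag(1 / se^2, nrow = length(y))
  solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
}

# raw polynomial design matrix, increasing powers
poly_X <- function(x, degree) {
  vapply(0:degree, function(k) x^k, numeric(length(x)))
}

# direct-loop boxcar with shrinking edge windows (3 left, 2 right)
boxcar_oracle <- function(y, left = 3, right = 2) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}

# window solid angle by brute-force midpoint integration of cos(ele)
window_solid_angle_oracle <- function(azi_min = -110, azi_max = 110,
                                      ele_min = -10, ele_max = 80,
                                      n = 2000) {
  ele <- seq(ele_min, ele_max, length.out = n + 1)
  mid <- (ele[-1] + ele[-(n + 1)]) / 2
  d_ele <- diff(ele) * pi / 180
  (azi_max - azi_min) * pi / 180 * sum(cos(mid * pi / 180) * d_ele)
}

# smooth nonlinear monotone dome model used for LUT tests: pixel coordinates
# in [0, 1919] x [0, 1079] map to angles with a mild cross-axis warp
dome_model <- function(x, y) {
  u <- x / 1919
  v <- y / 1079
  list(azi = -110 + 220 * u + 6 * u * (1 - u) * v,
       ele = -10 + 90 * v + 5 * v * (1 - v) * u)
}

dome_grid <- function(n_cols = 20, n_rows = 10) {
  xs <- seq(0, 1919, length.out = n_cols)
  ys <- seq(0, 1079, length.out = n_rows)
  g <- expand.grid(x = xs, y = ys)  # row-major: x fastest
  ang <- dome_model(g$x, g$y)
  data.frame(x = g$x, y = g$y, azi = ang$azi, ele = ang$ele)
}

# evaluate a fitted polynomial surface on a dense grid and return the argmax
grid_peak_oracle <- function(fit, lower, upper, n = 400) {
  g1 <- seq(lower[1], upper[1], length.out = n)
  g2 <- seq(lower[2], upper[2], length.out = n)
  z <- outer(g1, g2, function(a, b) predict(fit, list(x1 = a, x2 = b)))
  idx <- arrayInd(which.max(z), dim(z))
  list(location = c(g1[idx[1]], g2[idx[2]]), height = max(z),
       step = c(g1[2] - g1[1], g2[2] - g2[1]))
}

# closed-form first-order step response at time t after motion onset
step_oracle <- function(t, latency, tau) {
  ifelse(t < latency, 0, 1 - exp(-(t - latency) / tau))
}

# tiny per-trial OLR data frame builder for fold tests
fold_df <- function(mouse, speed, direction, olr, contrast = 0.68,
                    dot_radius = 1.4) {
  data.frame(mouse = mouse, speed = speed, direction = direction,
             contrast = contrast, dot_radius = dot_radius, olr = olr)
}
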