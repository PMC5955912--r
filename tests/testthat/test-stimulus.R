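test_that("dot sampling respects the window and the empty case", {
  w <- stimulus_window()
  expect_identical(nrow(sample_dot_field(0, w, 1.4, seed = 1)), 0L)
  f <- sample_dot_field(5000, w, 1.4, seed = 42)
  expect_true(all(f$azimuth >= -110 & f$azimuth <= 110))
  expect_true(all(f$elevation >= -10 & f$elevation <= 80))
  expect_error(sample_dot_field(-3, w), ">= 0")
})

test_that("elevation sampling is the arcsine transform: sin(ele) is uniform", {
  f <- sample_dot_field(10000, stimulus_window(), 1.4, seed = 7)
  s <- sin(f$elevation * pi / 180)
  ks <- ks.test(s, "punif", sin(-10 * pi / 180), sin(80 * pi / 180))
  expect_gt(ks$p.value, 0.01)
  # the untransformed elevations must NOT be uniform (density falls with
  # altitude), otherwise the transform did nothing
  ks2 <- ks.test(f$elevation, "punif", -10, 80)
  expect_lt(ks2$p.value, 0.01)
})

test_that("dot density is isotropic: equal-solid-angle bins are uniform", {
  f <- sample_dot_field(20000, stimulus_window(), 1.4, seed = 11)
  ia <- findInterval(f$azimuth, seq(-110, 110, length.out = 11),
                     rightmost.closed = TRUE)
  s_edges <- seq(sin(-10 * pi / 180), sin(80 * pi / 180), length.out = 11)
  ie <- findInterval(sin(f$elevation * pi / 180), s_edges,
                     rightmost.closed = TRUE)
  counts <- as.vector(table(factor(ia, 1:10), factor(ie, 1:10)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("window solid angle matches brute-force integration", {
  expect_equal(window_solid_angle(stimulus_window()),
               window_solid_angle_oracle(), tolerance = 1e-6)
})

test_that("dot-count rule keeps 27% coverage for all five assay radii", {
  w <- stimulus_window()
  expect_identical(dot_count_for_coverage(1.4, w, 0), 0L)
  # independent oracle: numeric window integration and the cap formula
  n_oracle <- round(0.27 * window_solid_angle_oracle() /
                      (2 * pi * (1 - cos(1.4 * pi / 180))))
  expect_equal(dot_count_for_coverage(1.4, w, 0.27), n_oracle)
  expect_equal(dot_count_for_coverage(1.4, w, 0.27), 640L)
  for (r in c(0.6, 0.9, 1.4, 2.3, 3.7)) {
    n <- dot_count_for_coverage(r, w, 0.27)
    rc <- realized_coverage(n, r, w)
    expect_equal(round(100 * rc), 27)
    expect_lt(abs(100 * rc - 27), 0.5)
  }
  expect_error(dot_count_for_coverage(1.4, w, 1), "< 1")
  expect_error(dot_count_for_coverage(60, w, 0.27), "too large")
})

test_that("advancing dots shifts azimuth with wrap-around and conserves the rest", {
  w <- stimulus_window()
  f <- sample_dot_field(200, w, 1.4, seed = 3)
  expect_equal(advance_dots(f, 0, "right")$azimuth, f$azimuth)
  # 2 s of 60 Hz frames at 72 deg/s: 120 frames x 1.2 deg = 144 deg net,
  # modulo the 220-degree window span (direct-sum oracle)
  g <- f
  for (k in 1:120) g <- advance_dots(g, 72, "right", 1 / 60)
  expected <- -110 + (f$azimuth + 120 * 72 / 60 + 110) %% 220
  expect_equal(g$azimuth, expected, tolerance = 1e-9)
  expect_equal(g$elevation, f$elevation)
  # single 60 Hz frame at 9 deg/s moves 0.15 degrees
  one <- advance_dots(f, 9, "left", 1 / 60)
  shift <- f$azimuth - one$azimuth
  expect_equal(shift[abs(shift) < 100], rep(0.15, sum(abs(shift) < 100)))
  # wrap conservation property over random speeds/durations
  set.seed(99)
  for (k in 1:10) {
    sp <- runif(1, 0, 100)
    g2 <- advance_dots(f, sp, sample(c("left", "right"), 1), runif(1, 0, 5))
    expect_identical(nrow(g2), nrow(f))
    expect_equal(g2$elevation, f$elevation)
    expect_true(all(g2$azimuth >= -110 & g2$azimuth <= 110))
  }
})

test_that("component-dot cluster is 21 dots in three rotation-symmetric rings", {
  for (r in c(0.6, 1.4, 3.7)) {
    lay <- component_dot_layout(r)
    expect_identical(nrow(lay), 21L)
    mag <- sqrt(lay$d_azi^2 + lay$d_ele^2)
    expect_lte(max(mag), r)
    # ring structure: concentric rings of 6, 7, 8 at increasing radii
    rings <- split(seq_len(21), round(mag, 10))
    expect_identical(lengths(rings, use.names = FALSE)[order(as.numeric(names(rings)))],
                     c(6L, 7L, 8L))
    # each ring maps onto itself under rotation by its own angular pitch
    for (ring in rings) {
      z <- complex(real = lay$d_azi[ring], imaginary = lay$d_ele[ring])
      zr <- z * exp(2i * pi / length(ring))
      d <- outer(zr, z, function(a, b) Mod(a - b))
      expect_lt(max(apply(d, 1, min)), 1e-10)
    }
  }
})

test_that("dot-field export writes the replay schema deterministically", {
  f <- sample_dot_field(10, stimulus_window(), 1.4, seed = 5)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_dot_field_csv(f, p1, n_frames = 3, speed = 36)
  write_dot_field_csv(f, p2, n_frames = 3, speed = 36)
  expect_identical(readLines(p1), readLines(p2))
  df <- read.csv(p1)
  expect_identical(names(df), c("frame", "dot_id", "azi_deg", "ele_deg"))
  expect_identical(nrow(df), 30L)
})
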