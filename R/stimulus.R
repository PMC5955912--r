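#' Stimulus window on the dome
#'
#' Describes the angular extent of the stimulus on the inside of the
#' projection dome. The defaults are a 220-degree horizontal window
#' (azimuth -110 to 110 degrees) reaching from 10 degrees below the mouse to
#' 80 degrees above it, on a dome with a 112 cm inner diameter.
#'
#' @param azi_min,azi_max Azimuth limits in degrees, `azi_min < azi_max`.
#' @param ele_min,ele_max Elevation limits in degrees, strictly inside
#'   (-90, 90) with `ele_min < ele_max`.
#' @param dome_diameter Inner diameter of the dome in cm (metadata only; all
#'   geometry is angular).
#' @return An object of class `olr_window`.
#' @examples
#' w <- stimulus_window()
#' window_solid_angle(w)  # ~4.45 sr
#' @export
stimulus_window <- function(azi_min = -110, azi_max = 110,
                            ele_min = -10, ele_max = 80,
                            dome_diameter = 112) {
  stopifnot_scalar(azi_min, "azi_min")
  stopifnot_scalar(azi_max, "azi_max")
  stopifnot_scalar(ele_min, "ele_min")
  stopifnot_scalar(ele_max, "ele_max")
  stopifnot_scalar(dome_diameter, "dome_diameter", positive = TRUE)
  if (azi_min >= azi_max) stop("`azi_min` must be < `azi_max`", call. = FALSE)
  if (!(-90 < ele_min && ele_min < ele_max && ele_max < 90)) {
    stop("need -90 < ele_min < ele_max < 90", call. = FALSE)
  }
  structure(
    list(azi_min = azi_min, azi_max = azi_max,
         ele_min = ele_min, ele_max = ele_max,
         dome_diameter = dome_diameter),
    class = "olr_window"
  )
}

#' @export
print.olr_window <- function(x, ...) {
  cat(sprintf(
    "Stimulus window: azimuth [%g, %g] deg, elevation [%g, %g] deg, dome %g cm\n",
    x$azi_min, x$azi_max, x$ele_min, x$ele_max, x$dome_diameter))
  invisible(x)
}

#' Solid angle of the stimulus window
#'
#' The window is an azimuthal band of a sphere, so its solid angle is the
#' azimuth span (in radians) times the difference of the sines of the
#' elevation limits.
#'
#' @param window An `olr_window`.
#' @return Solid angle in steradians.
#' @export
window_solid_angle <- function(window) {
  stopifnot(inherits(window, "olr_window"))
  (window$azi_max - window$azi_min) * pi / 180 *
    (sind(window$ele_max) - sind(window$ele_min))
}

#' Solid angle of one dot
#'
#' A dot of angular radius `r` is a spherical cap with solid angle
#' `2 * pi * (1 - cos r)` steradians (not the planar `pi r^2` approximation;
#' the difference is below 0.1\% at the radii used but the assay's geometry is
#' spherical throughout).
#'
#' @param dot_radius Dot radius in degrees.
#' @return Solid angle in steradians.
#' @export
dot_solid_angle <- function(dot_radius) {
  stopifnot_scalar(dot_radius, "dot_radius", positive = TRUE)
  2 * pi * (1 - cosd(dot_radius))
}

#' Sample an isotropic random dot field
#'
#' Dot azimuths are uniform over the azimuth window. Elevations are drawn by
#' taking the arcsine of a variate uniform on `[sin(ele_min), sin(ele_max)]`,
#' which makes the dot density isotropic on the sphere: without the arcsine
#' the density would pile up towards the zenith where horizontal circles
#' shrink.
#'
#' @param n_dots Number of dots (>= 0).
#' @param window An [stimulus_window()].
#' @param dot_radius Dot radius in degrees.
#' @param seed Optional integer seed; when given, sampling happens in a
#'   temporary RNG state and the caller's stream is untouched.
#' @return A `dot_field`: data frame with columns `azimuth`, `elevation`
#'   (degrees) and attributes `dot_radius` and `window`.
#' @examples
#' f <- sample_dot_field(100, stimulus_window(), dot_radius = 1.4, seed = 1)
#' range(f$azimuth)
#' @export
sample_dot_field <- function(n_dots, window = stimulus_window(),
                             dot_radius = 1.4, seed = NULL) {
  stopifnot_scalar(n_dots, "n_dots", nonneg = TRUE)
  stopifnot(inherits(window, "olr_window"))
  stopifnot_scalar(dot_radius, "dot_radius", positive = TRUE)
  n_dots <- as.integer(n_dots)
  with_seed(seed, {
    azi <- stats::runif(n_dots, window$azi_min, window$azi_max)
    ele <- asind(stats::runif(n_dots, sind(window$ele_min), sind(window$ele_max)))
    new_dot_field(azi, ele, dot_radius, window)
  })
}

new_dot_field <- function(azimuth, elevation, dot_radius, window) {
  structure(
    data.frame(azimuth = azimuth, elevation = elevation),
    dot_radius = dot_radius, window = window,
    class = c("dot_field", "data.frame")
  )
}

#' Number of dots for a target coverage
#'
#' The assay keeps the fraction of the display covered by dots constant
#' (27\% in all conditions) so that mean luminance does not change when dot
#' size is manipulated; the dot count is therefore inversely proportional to
#' the per-dot solid angle.
#'
#' @param dot_radius Dot radius in degrees.
#' @param window An [stimulus_window()].
#' @param coverage Target covered fraction, in `[0, 1)`.
#' @return Integer dot count `round(coverage * window_sr / dot_sr)`.
#' @examples
#' dot_count_for_coverage(1.4)  # 640 dots in the default window at 27%
#' @export
dot_count_for_coverage <- function(dot_radius, window = stimulus_window(),
                                   coverage = 0.27) {
  stopifnot(inherits(window, "olr_window"))
  stopifnot_scalar(coverage, "coverage", nonneg = TRUE)
  if (coverage >= 1) stop("`coverage` must be < 1", call. = FALSE)
  stopifnot_scalar(dot_radius, "dot_radius", positive = TRUE)
  extent <- min(window$azi_max - window$azi_min,
                window$ele_max - window$ele_min)
  if (2 * dot_radius >= extent) {
    stop("`dot_radius` too large for the stimulus window", call. = FALSE)
  }
  as.integer(round(coverage * window_solid_angle(window) /
                     dot_solid_angle(dot_radius)))
}

#' Realized dot coverage
#'
#' Covered fraction actually achieved by `n_dots` dots of the given radius
#' (ignoring overlap, as the on-screen density is low).
#'
#' @inheritParams dot_count_for_coverage
#' @param n_dots Dot count.
#' @return Fraction of the window solid angle covered.
#' @export
realized_coverage <- function(n_dots, dot_radius, window = stimulus_window()) {
  stopifnot_scalar(n_dots, "n_dots", nonneg = TRUE)
  n_dots * dot_solid_angle(dot_radius) / window_solid_angle(window)
}

#' Advance a dot field by horizontal motion
#'
#' Motion is a pure yaw rotation: each frame the azimuths are incremented
#' (rightward) or decremented (leftward) by `speed * dt`, and elevations are
#' untouched. Dots leaving the azimuth window re-enter at the opposite edge,
#' keeping count and density constant, consistent with constant coverage
#' during motion.
#'
#' @param field A `dot_field`.
#' @param speed Pattern speed in deg/s (>= 0).
#' @param direction `"right"` (azimuth increases) or `"left"`.
#' @param dt Time step in seconds (> 0); one 60 Hz video frame is 1/60 s.
#' @return The advanced `dot_field`.
#' @export
advance_dots <- function(field, speed, direction = c("right", "left"),
                         dt = 1 / 60) {
  stopifnot(inherits(field, "dot_field"))
  direction <- match.arg(direction)
  stopifnot_scalar(speed, "speed", nonneg = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  w <- attr(field, "window")
  span <- w$azi_max - w$azi_min
  shift <- speed * dt * if (direction == "right") 1 else -1
  azi <- w$azi_min + (field$azimuth - w$azi_min + shift) %% span
  new_dot_field(azi, field$elevation, attr(field, "dot_radius"), w)
}

#' Component-dot layout of one stimulus dot
#'
#' Each displayed "dot" is a cluster of 21 partially overlapping
#' component-dots arranged in three concentric rings around the dot center,
#' so that after each component is pushed through the projection lookup table
#' the cluster still looks circular from the mouse's viewpoint even where the
#' projector hits the dome obliquely. The ring radii and counts (6, 7 and 8
#' components at radii r/3, 2r/3 and 0.98 r, evenly spaced in angle with the
#' first component of each ring at 0 degrees) are one deterministic,
#' gap-free choice summing to exactly 21; only the cluster size and the
#' three-ring structure are fixed by the assay. The overlapping inner ring
#' covers the central position, so no separate center component is needed.
#'
#' @param dot_radius Dot radius in degrees.
#' @return A `component_layout`: data frame of offsets `d_azi`, `d_ele`
#'   (degrees, relative to the dot center) with attribute `dot_radius`.
#' @export
component_dot_layout <- function(dot_radius) {
  stopifnot_scalar(dot_radius, "dot_radius", positive = TRUE)
  counts <- c(6L, 7L, 8L)
  radii <- dot_radius * c(1 / 3, 2 / 3, 0.98)
  d_azi <- numeric(0)
  d_ele <- numeric(0)
  for (k in seq_along(counts)) {
    th <- 2 * pi * (seq_len(counts[k]) - 1L) / counts[k]
    d_azi <- c(d_azi, radii[k] * cos(th))
    d_ele <- c(d_ele, radii[k] * sin(th))
  }
  structure(
    data.frame(d_azi = d_azi, d_ele = d_ele),
    dot_radius = dot_radius,
    class = c("component_layout", "data.frame")
  )
}

#' Export a dot-field animation as CSV
#'
#' Writes frames of an advancing dot field in the renderer-agnostic replay
#' schema `frame,dot_id,azi_deg,ele_deg`.
#'
#' @param field Starting `dot_field`.
#' @param path Output CSV path.
#' @param n_frames Number of video frames to write.
#' @param speed,direction,dt Motion parameters passed to [advance_dots()].
#' @return `path`, invisibly.
#' @export
write_dot_field_csv <- function(field, path, n_frames = 1, speed = 0,
                                direction = "right", dt = 1 / 60) {
  stopifnot(inherits(field, "dot_field"))
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  rows <- vector("list", n_frames)
  cur <- field
  for (fr in seq_len(n_frames)) {
    rows[[fr]] <- data.frame(frame = fr, dot_id = seq_len(nrow(cur)),
                             azi_deg = cur$azimuth, ele_deg = cur$elevation)
    if (fr < n_frames) cur <- advance_dots(cur, speed, direction, dt)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
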