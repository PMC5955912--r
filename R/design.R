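# factor levels of the three assay experiments
olr_speeds_full <- function() seq(0, 72, by = 9)
olr_speeds_surface <- function() c(0, 18, 36, 54, 72)
olr_contrast_labels <- function() c(0.09, 0.37, 0.68, 0.89, 0.95)
olr_dot_luminances <- function() c(0.11, 0.20, 0.5, 1.66, 3.98)
olr_background_luminance <- function() 0.09
olr_dot_radii <- function() c(0.6, 0.9, 1.4, 2.3, 3.7)

#' Michelson contrast
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` for a dot luminance against the
#' background. With the assay's light-grey dots on a dark-grey background the
#' dot is always Lmax.
#'
#' @param dot_luminance,background_luminance Luminances in cd/m^2, > 0
#'   (vectorized).
#' @return Contrast fraction in `[0, 1)` for `dot >= background`.
#' @examples
#' michelson_contrast(3.98, 0.09)  # ~0.956
#' @export
michelson_contrast <- function(dot_luminance, background_luminance) {
  if (!is.numeric(dot_luminance) || !is.numeric(background_luminance) ||
      any(!is.finite(dot_luminance)) || any(!is.finite(background_luminance)) ||
      any(dot_luminance <= 0) || any(background_luminance <= 0)) {
    stop("luminances must be positive and finite", call. = FALSE)
  }
  hi <- pmax(dot_luminance, background_luminance)
  lo <- pmin(dot_luminance, background_luminance)
  (hi - lo) / (hi + lo)
}

#' Enumerate the stimulus conditions of one experiment
#'
#' Builds the full factorial condition grid of one of the three assay
#' experiments:
#' \describe{
#'   \item{`"speed"`}{9 speeds (0 to 72 deg/s in steps of 9) x 2 directions x
#'     2 motion-onset times = 36 conditions; contrast fixed at 0.68, dot
#'     radius at 1.4 degrees.}
#'   \item{`"contrast"`}{5 speeds (0, 18, 36, 54, 72 deg/s) x 2 directions x
#'     2 onset times x 5 Michelson contrasts = 100 conditions; radius 1.4.}
#'   \item{`"dotsize"`}{as `"contrast"` but with 5 dot radii (0.6 to 3.7
#'     degrees) at contrast 0.68 = 100 conditions.}
#' }
#' The zero-speed condition (with both direction labels retained) is part of
#' every grid: its trials provide the static-stimulus reference curve that is
#' subtracted from all motion conditions, and keeping both labels preserves
#' the factorial structure and the printed condition counts.
#'
#' Contrast conditions carry the dot luminance actually projected
#' (0.11 to 3.98 cd/m^2 on a 0.09 cd/m^2 background); the two-decimal
#' contrast labels are attached as given because recomputing them from the
#' rounded printed luminances disagrees with the labels in the second
#' decimal.
#'
#' @param experiment `"speed"`, `"contrast"` or `"dotsize"`.
#' @return An `olr_conditions` data frame with one row per condition and
#'   columns `speed`, `direction`, `static_pre`, `contrast`, `dot_radius`,
#'   `dot_luminance`, `background_luminance`.
#' @examples
#' nrow(make_conditions("speed"))     # 36
#' nrow(make_conditions("contrast"))  # 100
#' @export
make_conditions <- function(experiment = c("speed", "contrast", "dotsize")) {
  experiment <- match.arg(experiment)
  base <- switch(experiment,
    speed = expand.grid(
      speed = olr_speeds_full(), direction = c("left", "right"),
      static_pre = c(1, 2), contrast = 0.68, dot_radius = 1.4,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    contrast = expand.grid(
      speed = olr_speeds_surface(), direction = c("left", "right"),
      static_pre = c(1, 2), contrast = olr_contrast_labels(), dot_radius = 1.4,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    dotsize = expand.grid(
      speed = olr_speeds_surface(), direction = c("left", "right"),
      static_pre = c(1, 2), contrast = 0.68, dot_radius = olr_dot_radii(),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
  lum <- olr_dot_luminances()[match(base$contrast, olr_contrast_labels())]
  base$dot_luminance <- lum
  base$background_luminance <- olr_background_luminance()
  structure(base, experiment = experiment,
            class = c("olr_conditions", "data.frame"))
}

#' Build a randomized interleaved session schedule
#'
#' A session presents every condition the same number of times in a
#' randomly interleaved block design: the trial list is `repeats_per_session`
#' consecutive blocks, each an independent random permutation of the full
#' condition set (no constraint across block boundaries).
#'
#' @param conditions An [make_conditions()] data frame (or any data frame of
#'   conditions, one row each).
#' @param repeats_per_session Number of blocks (>= 1).
#' @param seed Optional seed for the permutations.
#' @param session_id Identifier stored on the schedule.
#' @return An `olr_schedule` data frame with columns `trial`, `block`, plus
#'   the condition columns.
#' @export
make_schedule <- function(conditions, repeats_per_session, seed = NULL,
                          session_id = 1L) {
  conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 0L) {
    stop("`conditions` must contain at least one condition", call. = FALSE)
  }
  stopifnot_scalar(repeats_per_session, "repeats_per_session", positive = TRUE)
  repeats_per_session <- as.integer(repeats_per_session)
  nc <- nrow(conditions)
  ord <- with_seed(seed, unlist(lapply(seq_len(repeats_per_session),
                                       function(b) sample.int(nc))))
  out <- conditions[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(trial = seq_len(nc * repeats_per_session),
               block = rep(seq_len(repeats_per_session), each = nc),
               out)
  structure(out, session_id = session_id,
            repeats_per_session = repeats_per_session,
            class = c("olr_schedule", "data.frame"))
}

#' Total repeats of each condition over a test
#'
#' Sessions present each condition `repeats_per_session` times and the
#' session plan is repeated `n_sessions` times, so each condition is seen
#' `repeats_per_session * n_sessions` times: 10 x 7 = 70 for the speed
#' experiment, 5 x 14 = 70 for the contrast and dot-size experiments.
#'
#' @param repeats_per_session,n_sessions Non-negative counts.
#' @return Their product.
#' @export
total_repeats <- function(repeats_per_session, n_sessions) {
  stopifnot_scalar(repeats_per_session, "repeats_per_session", nonneg = TRUE)
  stopifnot_scalar(n_sessions, "n_sessions", nonneg = TRUE)
  repeats_per_session * n_sessions
}

#' Per-trial stimulus timeline
#'
#' A trial starts with a static dot pattern for 1 or 2 s (randomly
#' interleaved so motion onset cannot be anticipated), then the pattern
#' drifts left or right for 2 s, then stays static for a final 1 s. Motion
#' onset defines t = 0 of the analysis.
#'
#' @param static_pre Initial static duration in seconds: 1 or 2.
#' @param fs Sampling rate in Hz (60 for the assay).
#' @return An `olr_timeline` list with elements `static_pre`, `motion`,
#'   `static_post`, `duration`, `motion_onset_time`, `fs`, `n_samples` and
#'   `t0_index` (1-based index of the first motion sample; sample `i` is
#'   taken at time `(i - 1) / fs` from trial start).
#' @export
trial_timeline <- function(static_pre, fs = 60) {
  if (!static_pre %in% c(1, 2)) {
    stop("`static_pre` must be 1 or 2 seconds", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs", positive = TRUE)
  duration <- static_pre + 2 + 1
  structure(
    list(static_pre = static_pre, motion = 2, static_post = 1,
         duration = duration, motion_onset_time = static_pre, fs = fs,
         n_samples = as.integer(round(duration * fs)),
         t0_index = as.integer(round(static_pre * fs)) + 1L),
    class = "olr_timeline"
  )
}

#' Read / write a session schedule CSV
#'
#' Schema `trial,block,speed_deg_s,direction,static_pre_s,contrast,dot_radius_deg`.
#'
#' @param schedule An [make_schedule()] result.
#' @param path CSV path.
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns the schedule data frame.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "olr_schedule"))
  df <- data.frame(
    trial = schedule$trial, block = schedule$block,
    speed_deg_s = schedule$speed, direction = schedule$direction,
    static_pre_s = schedule$static_pre, contrast = schedule$contrast,
    dot_radius_deg = schedule$dot_radius
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "block", "speed_deg_s", "direction", "static_pre_s",
            "contrast", "dot_radius_deg")
  if (!all(need %in% names(df))) {
    stop("schedule file is missing required columns", call. = FALSE)
  }
  out <- data.frame(
    trial = df$trial, block = df$block, speed = df$speed_deg_s,
    direction = df$direction, static_pre = df$static_pre_s,
    contrast = df$contrast, dot_radius = df$dot_radius_deg
  )
  structure(out, class = c("olr_schedule", "data.frame"))
}
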