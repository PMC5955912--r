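#' Response parameters of one simulated mouse
#'
#' The synthetic mouse turns with the stimulus: after a fixed latency its yaw
#' rises as a first-order (exponential) step response towards a plateau of
#' `gain_multiplier` times the cohort tuning value for the condition, and
#' decays the same way after motion offset. White Gaussian sample noise and a
#' per-trial constant baseline offset (slow forward-running drift) are added
#' on top. Real response dynamics and trial-to-trial variability are not
#' characterized for this assay, so these defaults are synthetic stand-ins
#' chosen to reproduce the phenomenology of the measured traces: a smooth
#' rise to plateau well within 1 s, so that the 1-2 s analysis window reads
#' the plateau (within 0.01\% with the defaults).
#'
#' @param gain_multiplier Dimensionless scaling of the tuning surface (> 0).
#' @param latency Response latency in seconds (>= 0).
#' @param time_constant Exponential time constant in seconds (> 0).
#' @param noise_sd White noise SD per 60 Hz sample, deg/s.
#' @param baseline_drift_sd SD of the per-trial constant yaw offset, deg/s.
#' @param peak_speed_scale Multiplicative shift of this mouse's preferred
#'   speed (1 = the cohort tuning peak).
#' @return A `mouse_params` list.
#' @export
mouse_params <- function(gain_multiplier = 1, latency = 0.1,
                         time_constant = 0.1, noise_sd = 10,
                         baseline_drift_sd = 5, peak_speed_scale = 1) {
  stopifnot_scalar(gain_multiplier, "gain_multiplier", positive = TRUE)
  stopifnot_scalar(latency, "latency", nonneg = TRUE)
  stopifnot_scalar(time_constant, "time_constant", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(baseline_drift_sd, "baseline_drift_sd", nonneg = TRUE)
  stopifnot_scalar(peak_speed_scale, "peak_speed_scale", positive = TRUE)
  structure(list(gain_multiplier = gain_multiplier, latency = latency,
                 time_constant = time_constant, noise_sd = noise_sd,
                 baseline_drift_sd = baseline_drift_sd,
                 peak_speed_scale = peak_speed_scale),
            class = "mouse_params")
}

#' Ground-truth tuning surface for simulation
#'
#' A known plateau-yaw tuning `f(speed, contrast, dot_radius)` used as
#' simulation truth: a concave quadratic in speed that is zero at speed 0 and
#' maximal (value `peak_olr`) at `peak_speed`, multiplied by saturating
#' (Naka-Rushton style) factors in contrast and dot radius that equal 1 at
#' the reference contrast 0.68 and radius 1.4 degrees. In the speed
#' experiment (run at the reference contrast and radius) the true tuning
#' peak is therefore exactly `(peak_speed, peak_olr)`.
#'
#' @param peak_speed Speed of maximal response, deg/s (> 0).
#' @param peak_olr Plateau yaw at the peak, deg/s.
#' @param contrast_semisat Contrast semi-saturation constant.
#' @param size_semisat Dot-radius semi-saturation constant, degrees.
#' @return An `olr_tuning` object; evaluate it with [tuning_eval()].
#' @export
default_tuning <- function(peak_speed = 57.2, peak_olr = 35,
                           contrast_semisat = 0.2, size_semisat = 0.5) {
  stopifnot_scalar(peak_speed, "peak_speed", positive = TRUE)
  stopifnot_scalar(peak_olr, "peak_olr")
  structure(list(peak_speed = peak_speed, peak_olr = peak_olr,
                 contrast_semisat = contrast_semisat,
                 size_semisat = size_semisat,
                 contrast_ref = 0.68, size_ref = 1.4),
            class = "olr_tuning")
}

#' Evaluate a tuning surface
#'
#' @param tuning An [default_tuning()] object.
#' @param speed,contrast,dot_radius Condition values (vectorized).
#' @param peak_speed_scale Per-mouse multiplicative shift of the preferred
#'   speed.
#' @return Plateau yaw in deg/s; 0 at `speed = 0` by construction.
#' @export
tuning_eval <- function(tuning, speed, contrast = tuning$contrast_ref,
                        dot_radius = tuning$size_ref, peak_speed_scale = 1) {
  stopifnot(inherits(tuning, "olr_tuning"))
  u <- speed / (tuning$peak_speed * peak_speed_scale)
  cf <- (contrast / (contrast + tuning$contrast_semisat)) /
    (tuning$contrast_ref / (tuning$contrast_ref + tuning$contrast_semisat))
  sf <- (dot_radius / (dot_radius + tuning$size_semisat)) /
    (tuning$size_ref / (tuning$size_ref + tuning$size_semisat))
  tuning$peak_olr * (2 * u - u^2) * cf * sf
}

# normalized first-order step response sampled on a trial timeline: 0 until
# motion onset + latency, 1 - exp(-(t - t0 - latency)/tau) while driven,
# exponential decay after offset + latency; closed form, no integration
step_response_shape <- function(timeline, latency, time_constant) {
  t <- (seq_len(timeline$n_samples) - 1) / timeline$fs
  on <- timeline$motion_onset_time + latency
  off <- timeline$motion_onset_time + timeline$motion + latency
  s <- numeric(timeline$n_samples)
  rise <- t >= on & t < off
  s[rise] <- 1 - exp(-(t[rise] - on) / time_constant)
  s_off <- 1 - exp(-timeline$motion / time_constant)
  after <- t >= off
  s[after] <- s_off * exp(-(t[after] - off) / time_constant)
  s
}

#' Simulate one trial's yaw trace
#'
#' Yaw (analysis-facing sign: positive = turning with the stimulus) is
#' `drift + sign(direction) * gain_multiplier * f(condition) * step(t) +
#' noise`, where `f` is the tuning surface, `step` the first-order response
#' shape and `sign` is +1 for rightward and -1 for leftward motion.
#' Zero-speed trials contain only drift and noise.
#'
#' @param condition A one-row condition (list or data frame row) with fields
#'   `speed`, `direction`, `static_pre`, `contrast`, `dot_radius`.
#' @param mouse A [mouse_params()].
#' @param tuning An [default_tuning()] surface.
#' @param seed Optional seed.
#' @return A `yaw_trace`: list with `yaw` (deg/s at 60 Hz), `fs`,
#'   `t0_index`, and `condition`.
#' @export
simulate_trial <- function(condition, mouse = mouse_params(),
                           tuning = default_tuning(), seed = NULL) {
  condition <- as.list(condition)
  tl <- trial_timeline(condition$static_pre)
  dir_sign <- if (identical(condition$direction, "left")) -1 else 1
  amp <- if (condition$speed == 0) 0 else {
    dir_sign * mouse$gain_multiplier *
      tuning_eval(tuning, condition$speed, condition$contrast,
                  condition$dot_radius, mouse$peak_speed_scale)
  }
  shape <- step_response_shape(tl, mouse$latency, mouse$time_constant)
  with_seed(seed, {
    drift <- stats::rnorm(1, 0, mouse$baseline_drift_sd)
    noise <- stats::rnorm(tl$n_samples, 0, mouse$noise_sd)
    structure(list(yaw = amp * shape + drift + noise, fs = tl$fs,
                   t0_index = tl$t0_index, condition = condition),
              class = "yaw_trace")
  })
}

#' Cohort-level simulation settings
#'
#' Per-mouse gain multipliers are log-spaced over a `gain_spread`-fold range
#' (the measured cohort showed an almost threefold difference between the
#' weakest and strongest responder) and rescaled to mean 1, so the
#' population-mean response equals the tuning truth. Optionally a lognormal
#' jitter of each mouse's preferred speed (`peak_jitter_sd`, log-scale SD)
#' adds across-mouse tuning-shape spread; the default is 0 because the
#' point-level bootstrap used downstream treats the mouse x condition points
#' as exchangeable and does not model mouse-correlated shape deviations, so
#' shape heterogeneity widens the estimator's true sampling error beyond the
#' reported intervals.
#'
#' @param gain_spread Max/min ratio of per-mouse gain multipliers (>= 1).
#' @param peak_jitter_sd Log-scale SD of the per-mouse preferred-speed
#'   multiplier.
#' @param latency,time_constant,noise_sd,baseline_drift_sd Shared
#'   [mouse_params()] values.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(gain_spread = 3, peak_jitter_sd = 0,
                        latency = 0.1, time_constant = 0.1,
                        noise_sd = 10, baseline_drift_sd = 5) {
  if (gain_spread < 1) stop("`gain_spread` must be >= 1", call. = FALSE)
  stopifnot_scalar(peak_jitter_sd, "peak_jitter_sd", nonneg = TRUE)
  structure(list(gain_spread = gain_spread, peak_jitter_sd = peak_jitter_sd,
                 latency = latency, time_constant = time_constant,
                 noise_sd = noise_sd, baseline_drift_sd = baseline_drift_sd),
            class = "cohort_spec")
}

draw_cohort_mice <- function(n_mice, cohort) {
  g <- if (n_mice == 1L) 1 else {
    exp(seq(-log(cohort$gain_spread) / 2, log(cohort$gain_spread) / 2,
            length.out = n_mice))
  }
  g <- g / mean(g)
  ps <- exp(stats::rnorm(n_mice, 0, cohort$peak_jitter_sd))
  data.frame(mouse = seq_len(n_mice), gain_multiplier = g,
             peak_speed_scale = ps)
}

#' Simulate a full cohort experiment
#'
#' Generates every trial of one experiment for a simulated cohort: for each
#' mouse and session a fresh randomized interleaved schedule is drawn and
#' each trial's 60 Hz yaw trace is simulated from the mouse's parameters and
#' the ground-truth tuning. The full assay-scale defaults are 6 mice with 10
#' repeats x 7 sessions (speed experiment) or 5 repeats x 14 sessions
#' (contrast / dot-size), i.e. 70 repeats of every condition.
#'
#' @param experiment `"speed"`, `"contrast"` or `"dotsize"`.
#' @param n_mice Number of mice (>= 1).
#' @param repeats_per_session,n_sessions Session plan; defaults follow the
#'   experiment.
#' @param cohort A [cohort_spec()].
#' @param tuning Ground-truth [default_tuning()].
#' @param seed Seed; the same seed reproduces the dataset exactly.
#' @return An `olr_trials` object: list with
#'   \describe{
#'     \item{meta}{data frame, one row per trial: `mouse`, `session`,
#'       `block`, `trial`, condition columns, `t0_index`, `n_samples`.}
#'     \item{yaw}{matrix (trials x samples, NA-padded to the longest trial)
#'       of yaw in deg/s, analysis-facing sign.}
#'     \item{fs}{sampling rate, 60 Hz.}
#'     \item{mice}{per-mouse true parameters.}
#'     \item{tuning}{the ground-truth tuning object.}
#'   }
#' @export
simulate_cohort <- function(experiment = c("speed", "contrast", "dotsize"),
                            n_mice = 6,
                            repeats_per_session = NULL, n_sessions = NULL,
                            cohort = cohort_spec(),
                            tuning = default_tuning(), seed = NULL) {
  experiment <- match.arg(experiment)
  stopifnot_scalar(n_mice, "n_mice", positive = TRUE)
  n_mice <- as.integer(n_mice)
  if (is.null(repeats_per_session)) {
    repeats_per_session <- if (experiment == "speed") 10L else 5L
  }
  if (is.null(n_sessions)) {
    n_sessions <- if (experiment == "speed") 7L else 14L
  }
  conds <- make_conditions(experiment)
  with_seed(seed, {
    mice <- draw_cohort_mice(n_mice, cohort)
    scheds <- vector("list", n_mice * n_sessions)
    k <- 0L
    for (m in seq_len(n_mice)) {
      for (s in seq_len(n_sessions)) {
        k <- k + 1L
        sch <- make_schedule(conds, repeats_per_session, session_id = s)
        sch <- cbind(mouse = m, session = s, as.data.frame(sch))
        scheds[[k]] <- sch
      }
    }
    meta <- do.call(rbind, scheds)
    rownames(meta) <- NULL
    tls <- lapply(c(1, 2), trial_timeline)
    names(tls) <- c("1", "2")
    meta$t0_index <- vapply(tls, `[[`, integer(1), "t0_index")[
      as.character(meta$static_pre)]
    meta$n_samples <- vapply(tls, `[[`, integer(1), "n_samples")[
      as.character(meta$static_pre)]
    n_max <- max(meta$n_samples)
    yaw <- matrix(NA_real_, nrow(meta), n_max)
    amp <- ifelse(meta$direction == "right", 1, -1) *
      mice$gain_multiplier[meta$mouse] *
      tuning_eval(tuning, meta$speed, meta$contrast, meta$dot_radius,
                  mice$peak_speed_scale[meta$mouse])
    amp[meta$speed == 0] <- 0
    for (sp in c(1, 2)) {
      rows <- which(meta$static_pre == sp)
      tl <- tls[[as.character(sp)]]
      shape <- step_response_shape(tl, cohort$latency, cohort$time_constant)
      n <- tl$n_samples
      drift <- stats::rnorm(length(rows), 0, cohort$baseline_drift_sd)
      block <- amp[rows] %o% shape + drift +
        matrix(stats::rnorm(length(rows) * n, 0, cohort$noise_sd),
               length(rows), n)
      yaw[rows, seq_len(n)] <- block
    }
    structure(list(meta = meta, yaw = yaw, fs = 60, mice = mice,
                   tuning = tuning, experiment = experiment),
              class = "olr_trials")
  })
}

#' @export
print.olr_trials <- function(x, ...) {
  cat(sprintf("OLR trial dataset (%s experiment): %d trials, %d mice, %d sessions, %d Hz\n",
              x$experiment, nrow(x$meta), length(unique(x$meta$mouse)),
              length(unique(x$meta$session)), x$fs))
  invisible(x)
}
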