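#' Default analysis configuration
#'
#' All assay defaults in one place: the condition grids (speeds 0-72 deg/s in
#' steps of 9, the five Michelson contrasts, the five dot radii), the session
#' plans, 200 bootstrap resamples, alpha = 0.05, the 100-ms boxcar, the
#' 500-ms baseline window and the 1-2 s OLR window.
#'
#' @return A named list of class `olr_config`.
#' @export
default_config <- function() {
  structure(list(
    experiment = "speed",
    n_mice = 6L,
    repeats_per_session = 10L,
    n_sessions = 7L,
    speeds = olr_speeds_full(),
    contrasts = olr_contrast_labels(),
    dot_radii = olr_dot_radii(),
    boot_B = 200L,
    alpha = 0.05,
    smooth_width_s = 0.1,
    baseline_s = 0.5,
    olr_window = c(1, 2),
    seed = 1L,
    cohort = list(gain_spread = 3, peak_jitter_sd = 0, latency = 0.1,
                  time_constant = 0.1, noise_sd = 10, baseline_drift_sd = 5)
  ), class = c("olr_config", "list"))
}

validate_config <- function(cfg) {
  if (!cfg$experiment %in% c("speed", "contrast", "dotsize")) {
    stop("config error at `experiment`: unknown experiment", call. = FALSE)
  }
  num_ok <- function(x, key, min = -Inf, len = NULL) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
        (!is.null(len) && length(x) != len)) {
      stop(sprintf("config error at `%s`: invalid value", key), call. = FALSE)
    }
  }
  num_ok(cfg$n_mice, "n_mice", 1, 1)
  num_ok(cfg$repeats_per_session, "repeats_per_session", 1, 1)
  num_ok(cfg$n_sessions, "n_sessions", 1, 1)
  num_ok(cfg$speeds, "speeds", 0)
  num_ok(cfg$contrasts, "contrasts", 0)
  if (any(cfg$contrasts > 1)) stop("config error at `contrasts`: > 1",
                                   call. = FALSE)
  num_ok(cfg$dot_radii, "dot_radii", 0)
  if (any(cfg$dot_radii == 0)) stop("config error at `dot_radii`: must be > 0",
                                    call. = FALSE)
  num_ok(cfg$boot_B, "boot_B", 2, 1)
  num_ok(cfg$alpha, "alpha", 0, 1)
  if (cfg$alpha >= 1) stop("config error at `alpha`: must be < 1",
                           call. = FALSE)
  num_ok(cfg$smooth_width_s, "smooth_width_s", 0, 1)
  num_ok(cfg$baseline_s, "baseline_s", 0, 1)
  num_ok(cfg$olr_window, "olr_window", 0, 2)
  if (cfg$olr_window[1] >= cfg$olr_window[2]) {
    stop("config error at `olr_window`: start must precede end",
         call. = FALSE)
  }
  num_ok(cfg$seed, "seed", len = 1)
  for (k in names(cfg$cohort)) {
    num_ok(cfg$cohort[[k]], paste0("cohort.", k), 0, 1)
  }
  cfg
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file, fills every missing key with its [default_config()]
#' value, rejects unknown keys (reporting the key path) and validates the
#' result. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `olr_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist", call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config error: top level must be a mapping",
                           call. = FALSE)
  cfg <- default_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop(sprintf("config error: unknown key `%s`", bad[1]), call. = FALSE)
  }
  for (k in setdiff(names(user), "cohort")) cfg[[k]] <- user[[k]]
  if (!is.null(user$cohort)) {
    badc <- setdiff(names(user$cohort), names(cfg$cohort))
    if (length(badc)) {
      stop(sprintf("config error: unknown key `cohort.%s`", badc[1]),
           call. = FALSE)
    }
    for (k in names(user$cohort)) cfg$cohort[[k]] <- user$cohort[[k]]
  }
  validate_config(cfg)
}

#' Write / read a trial dataset as tidy CSV
#'
#' The sample file has one row per 60 Hz sample
#' (`mouse,session,trial,speed_deg_s,direction,static_pre_s,contrast,dot_radius_deg,sample,t_s,yaw_deg_s`);
#' the metadata file has one row per trial. Together they round-trip an
#' `olr_trials` object (up to the text representation of doubles; values are
#' written with 17 significant digits). Ground-truth fields of simulated
#' datasets are not part of the interchange schema.
#'
#' @param trials An `olr_trials` object.
#' @param samples_path,meta_path Output CSV paths.
#' @return `write_trials_csv()` returns the paths invisibly;
#'   `read_trials_csv()` returns an `olr_trials` object.
#' @export
write_trials_csv <- function(trials, samples_path, meta_path) {
  stopifnot(inherits(trials, "olr_trials"))
  meta <- trials$meta
  meta_out <- data.frame(
    mouse = meta$mouse, session = meta$session, trial = meta$trial,
    block = meta$block, speed_deg_s = meta$speed, direction = meta$direction,
    static_pre_s = meta$static_pre, contrast = meta$contrast,
    dot_radius_deg = meta$dot_radius, n_samples = meta$n_samples,
    t0_index = meta$t0_index
  )
  utils::write.csv(meta_out, meta_path, row.names = FALSE, quote = FALSE)
  ns <- meta$n_samples
  row_id <- rep(seq_len(nrow(meta)), ns)
  sample_id <- sequence(ns)
  yaw <- trials$yaw[cbind(row_id, sample_id)]
  samples <- data.frame(
    mouse = meta$mouse[row_id], session = meta$session[row_id],
    trial = meta$trial[row_id], speed_deg_s = meta$speed[row_id],
    direction = meta$direction[row_id],
    static_pre_s = meta$static_pre[row_id],
    contrast = meta$contrast[row_id],
    dot_radius_deg = meta$dot_radius[row_id],
    sample = sample_id,
    t_s = (sample_id - 1) / trials$fs,
    yaw_deg_s = sprintf("%.17g", yaw)
  )
  utils::write.csv(samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(c(samples = samples_path, meta = meta_path))
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(samples_path, meta_path) {
  meta_in <- utils::read.csv(meta_path)
  samples <- utils::read.csv(samples_path)
  meta <- data.frame(
    mouse = meta_in$mouse, session = meta_in$session, trial = meta_in$trial,
    block = meta_in$block, speed = meta_in$speed_deg_s,
    direction = meta_in$direction, static_pre = meta_in$static_pre_s,
    contrast = meta_in$contrast, dot_radius = meta_in$dot_radius_deg,
    t0_index = meta_in$t0_index, n_samples = meta_in$n_samples
  )
  yaw <- matrix(NA_real_, nrow(meta), max(meta$n_samples))
  row_id <- rep(seq_len(nrow(meta)), meta$n_samples)
  if (length(row_id) != nrow(samples)) {
    stop("sample file does not match trial metadata", call. = FALSE)
  }
  yaw[cbind(row_id, samples$sample)] <- samples$yaw_deg_s
  structure(list(meta = meta, yaw = yaw, fs = 60, mice = NULL, tuning = NULL,
                 experiment = "unknown"),
            class = "olr_trials")
}

#' Write an OLR table and condition summary as CSV
#'
#' Table schema
#' `mouse,speed,contrast,dot_radius,olr_deg_s,olr_norm,gain`; summary schema
#' `speed,contrast,dot_radius,n,mean,sem,p_value,significant`.
#'
#' @param olr_table A normalized, gain-augmented `olr_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_olr_table_csv <- function(olr_table, path) {
  out <- data.frame(
    mouse = olr_table$mouse, speed = olr_table$speed,
    contrast = olr_table$contrast, dot_radius = olr_table$dot_radius,
    olr_deg_s = olr_table$olr,
    olr_norm = if ("olr_norm" %in% names(olr_table)) olr_table$olr_norm else NA,
    gain = if ("gain" %in% names(olr_table)) olr_table$gain else NA
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_olr_table_csv
#' @param summary An `olr_summary` from [condition_summary()].
#' @export
write_summary_csv <- function(summary, path) {
  out <- data.frame(
    speed = summary$speed, contrast = summary$contrast,
    dot_radius = summary$dot_radius, n = summary$n, mean = summary$mean,
    sem = summary$sem, p_value = summary$p.value,
    significant = summary$significant
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a small deterministic test fixture
#'
#' Simulates a miniature cohort (3 mice, 1 session) with known ground truth
#' and writes it under `dir` as the trial-sample and metadata CSVs plus a
#' JSON sidecar recording the simulation truth (tuning peak, per-mouse
#' parameters, seed). The same seed always produces byte-identical files.
#'
#' @param kind `"tiny_speed"` (3 repeats of the 36 speed-experiment
#'   conditions) or `"tiny_surface"` (2 repeats of the 100 contrast-experiment
#'   conditions).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
generate_fixture <- function(kind = c("tiny_speed", "tiny_surface"),
                             seed = 1, dir = tempdir()) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials <- if (kind == "tiny_speed") {
    simulate_cohort("speed", n_mice = 3, repeats_per_session = 3,
                    n_sessions = 1, seed = seed)
  } else {
    simulate_cohort("contrast", n_mice = 3, repeats_per_session = 2,
                    n_sessions = 1, seed = seed)
  }
  samples_path <- file.path(dir, paste0(kind, "_samples.csv"))
  meta_path <- file.path(dir, paste0(kind, "_meta.csv"))
  truth_path <- file.path(dir, paste0(kind, "_truth.json"))
  write_trials_csv(trials, samples_path, meta_path)
  truth <- list(kind = kind, seed = seed,
                tuning = unclass(trials$tuning),
                mice = trials$mice)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(samples = samples_path, meta = meta_path, truth = truth_path))
}
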