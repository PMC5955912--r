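# boxcar-smooth one numeric vector: centred 100-ms moving average, 6 samples
# at 60 Hz split 3 left / 2 right of the current sample, windows shrinking at
# the trace edges
boxcar_vec <- function(y, left, right) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smooth_window_samples <- function(fs, width_s) {
  w <- as.integer(round(width_s * fs))
  if (w < 1L) stop("smoothing window shorter than one sample", call. = FALSE)
  left <- as.integer(ceiling((w - 1L) / 2))
  c(width = w, left = left, right = w - 1L - left)
}

#' Boxcar-smooth a yaw trace
#'
#' 100-ms moving-average filter, i.e. exactly 6 samples at 60 Hz. The window
#' is centred (3 samples left, 2 right of the current one, the filter phase
#' being otherwise unconstrained) and shrinks at the trace edges; a centred
#' window avoids biasing the latency of the downstream analysis window.
#'
#' @param trace A `yaw_trace` (see [simulate_trial()]) or a numeric vector.
#' @param fs Sampling rate in Hz (taken from the trace if present).
#' @param width_s Filter width in seconds.
#' @return Same type as the input, smoothed.
#' @export
smooth_yaw <- function(trace, fs = 60, width_s = 0.1) {
  if (inherits(trace, "yaw_trace")) {
    w <- smooth_window_samples(trace$fs, width_s)
    if (length(trace$yaw) < w["width"]) {
      stop("trace shorter than the smoothing window", call. = FALSE)
    }
    trace$yaw <- boxcar_vec(trace$yaw, w["left"], w["right"])
    return(trace)
  }
  w <- smooth_window_samples(fs, width_s)
  if (length(trace) < w["width"]) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  boxcar_vec(as.numeric(trace), w["left"], w["right"])
}

#' Subtract the pre-motion baseline
#'
#' The mean yaw over the final 500 ms (30 samples at 60 Hz) before motion
#' onset is subtracted from the whole trace, removing the forward-running
#' yaw offset of the trial.
#'
#' @param trace A `yaw_trace`, or a numeric vector with `t0_index` given.
#' @param t0_index 1-based index of the first motion sample (for numeric
#'   input).
#' @param fs Sampling rate in Hz.
#' @param baseline_s Baseline window length in seconds.
#' @return Same type as the input, baseline-corrected.
#' @export
subtract_baseline <- function(trace, t0_index = NULL, fs = 60,
                              baseline_s = 0.5) {
  if (inherits(trace, "yaw_trace")) {
    y <- trace$yaw
    t0_index <- trace$t0_index
    fs <- trace$fs
  } else {
    y <- as.numeric(trace)
    if (is.null(t0_index)) stop("`t0_index` required for numeric input",
                                call. = FALSE)
  }
  nb <- as.integer(round(baseline_s * fs))
  if (t0_index - nb < 1L) {
    stop("fewer pre-onset samples than the baseline window", call. = FALSE)
  }
  b <- mean(y[(t0_index - nb):(t0_index - 1L)])
  if (inherits(trace, "yaw_trace")) {
    trace$yaw <- y - b
    trace
  } else {
    y - b
  }
}

#' OLR scalar of one trace
#'
#' The opto-locomotor response of a trial is the mean baseline-corrected yaw
#' in the window from 1 to 2 s after motion onset. The window is half-open,
#' `[t0 + 1, t0 + 2)`, i.e. exactly 60 samples at 60 Hz, so the boundary
#' sample is not counted twice by adjacent windows.
#'
#' @inheritParams subtract_baseline
#' @param window Window start and end in seconds after motion onset.
#' @return Mean yaw in deg/s.
#' @export
olr_scalar <- function(trace, t0_index = NULL, fs = 60, window = c(1, 2)) {
  if (inherits(trace, "yaw_trace")) {
    y <- trace$yaw
    t0_index <- trace$t0_index
    fs <- trace$fs
  } else {
    y <- as.numeric(trace)
    if (is.null(t0_index)) stop("`t0_index` required for numeric input",
                                call. = FALSE)
  }
  i0 <- t0_index + as.integer(round(window[1] * fs))
  i1 <- t0_index + as.integer(round(window[2] * fs)) - 1L
  if (i1 > length(y)) stop("trace does not extend to the end of the OLR window",
                           call. = FALSE)
  mean(y[i0:i1])
}

# smooth + baseline-correct all rows of an olr_trials object; returns the
# corrected yaw matrix (same shape, NA padding preserved)
correct_trial_matrix <- function(trials, width_s = 0.1, baseline_s = 0.5) {
  Y <- trials$yaw
  w <- smooth_window_samples(trials$fs, width_s)
  nb <- as.integer(round(baseline_s * trials$fs))
  out <- Y
  for (n in sort(unique(trials$meta$n_samples))) {
    rows <- which(trials$meta$n_samples == n)
    B <- Y[rows, seq_len(n), drop = FALSE]
    # boxcar via a banded smoothing matrix (n is small, <= 300)
    i <- seq_len(n)
    lo <- pmax(i - w["left"], 1L)
    hi <- pmin(i + w["right"], n)
    S <- matrix(0, n, n)
    for (k in i) S[lo[k]:hi[k], k] <- 1 / (hi[k] - lo[k] + 1L)
    B <- B %*% S
    t0 <- trials$meta$t0_index[rows]
    for (t0v in unique(t0)) {
      grp <- t0 == t0v
      base <- rowMeans(B[grp, (t0v - nb):(t0v - 1L), drop = FALSE])
      B[grp, ] <- B[grp, , drop = FALSE] - base
    }
    out[rows, seq_len(n)] <- B
  }
  out
}

#' Per-trial OLR scalars for a whole dataset
#'
#' Applies the full trace preprocessing to every trial: boxcar smoothing
#' first, then baseline subtraction (that order matters slightly for the
#' baseline value), then the 1-2 s window mean.
#'
#' @param trials An `olr_trials` object from [simulate_cohort()] or
#'   [read_trials_csv()].
#' @param width_s,baseline_s,window Preprocessing parameters, see
#'   [smooth_yaw()], [subtract_baseline()], [olr_scalar()].
#' @return Data frame, one row per trial: the trial metadata plus `olr`.
#' @export
compute_trial_olrs <- function(trials, width_s = 0.1, baseline_s = 0.5,
                               window = c(1, 2)) {
  stopifnot(inherits(trials, "olr_trials"))
  B <- correct_trial_matrix(trials, width_s, baseline_s)
  fs <- trials$fs
  t0 <- trials$meta$t0_index
  i0 <- t0 + as.integer(round(window[1] * fs))
  i1 <- t0 + as.integer(round(window[2] * fs)) - 1L
  olr <- numeric(nrow(B))
  for (t0v in unique(t0)) {
    rows <- which(t0 == t0v)
    olr[rows] <- rowMeans(B[rows, i0[rows[1]]:i1[rows[1]], drop = FALSE])
  }
  cbind(trials$meta, olr = olr)
}

# per-mouse x condition mean OLR (pooling sessions and onset times)
aggregate_mouse_condition <- function(trial_olrs) {
  agg <- stats::aggregate(olr ~ mouse + speed + direction + contrast +
                            dot_radius, data = trial_olrs, FUN = mean)
  agg[order(agg$mouse, agg$contrast, agg$dot_radius, agg$speed,
            agg$direction), , drop = FALSE]
}

#' Zero-speed correction and direction folding of OLR scalars
#'
#' Per mouse (and per level of the extra factor in the surface experiments),
#' the zero-speed response is subtracted from every motion condition and the
#' matched rightward/leftward pair is averaged after flipping the sign of the
#' leftward member:
#' `OLR(s) = ((R(s) - Z) + (-1) (L(s) - Z)) / 2`.
#' The zero-speed trials of both direction labels are pooled into the single
#' reference `Z`, so the corrected zero-speed response is identically zero
#' and is not part of the returned table (fits and gains use the nonzero
#' speeds only).
#'
#' @param trial_olrs Per-trial OLR table from [compute_trial_olrs()].
#' @return An `olr_table` data frame: `mouse`, `speed` (> 0), `contrast`,
#'   `dot_radius`, `olr`.
#' @export
fold_olr_table <- function(trial_olrs) {
  agg <- aggregate_mouse_condition(trial_olrs)
  if (!any(agg$speed == 0)) {
    stop("zero-speed condition missing: cannot apply zero-speed correction",
         call. = FALSE)
  }
  out <- list()
  for (m in unique(agg$mouse)) {
    am <- agg[agg$mouse == m, , drop = FALSE]
    for (co in unique(am$contrast)) {
      for (dr in unique(am$dot_radius[am$contrast == co])) {
        cell <- am[am$contrast == co & am$dot_radius == dr, , drop = FALSE]
        z_rows <- cell[cell$speed == 0, , drop = FALSE]
        if (nrow(z_rows) == 0L) {
          stop("zero-speed condition missing for a factor level", call. = FALSE)
        }
        z <- mean(z_rows$olr)
        for (sp in sort(unique(cell$speed[cell$speed > 0]))) {
          r <- cell$olr[cell$speed == sp & cell$direction == "right"]
          l <- cell$olr[cell$speed == sp & cell$direction == "left"]
          if (length(r) != 1L || length(l) != 1L) {
            stop(sprintf(
              "missing left/right pair member at speed %g", sp), call. = FALSE)
          }
          out[[length(out) + 1L]] <- data.frame(
            mouse = m, speed = sp, contrast = co, dot_radius = dr,
            olr = ((r - z) - (l - z)) / 2)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("olr_table", "data.frame"))
}

#' Zero-speed correction and folding of mean traces
#'
#' Trace-level analogue of [fold_olr_table()]: per mouse and factor level,
#' trial traces (smoothed, baseline-corrected, aligned at motion onset over
#' the window -1 s to +3 s) are averaged per condition; the pooled zero-speed
#' mean trace is subtracted from each motion curve and matched left/right
#' pairs are folded. The zero-speed curve itself folds to exactly zero and
#' is included as such.
#'
#' @inheritParams compute_trial_olrs
#' @return An `olr_curves` object: list with `info` (data frame `mouse`,
#'   `speed`, `contrast`, `dot_radius`), `curves` (matrix, one row per info
#'   row, 240 samples), `t` (time relative to motion onset, seconds), `fs`.
#' @export
baseline_correct_curves <- function(trials, width_s = 0.1, baseline_s = 0.5) {
  stopifnot(inherits(trials, "olr_trials"))
  B <- correct_trial_matrix(trials, width_s, baseline_s)
  fs <- trials$fs
  pre <- fs           # 1 s before onset
  post <- 3 * fs      # motion + final static second
  t0 <- trials$meta$t0_index
  A <- matrix(NA_real_, nrow(B), pre + post)
  for (t0v in unique(t0)) {
    rows <- which(t0 == t0v)
    A[rows, ] <- B[rows, (t0v - pre):(t0v + post - 1L), drop = FALSE]
  }
  meta <- trials$meta
  key <- paste(meta$mouse, meta$speed, meta$direction, meta$contrast,
               meta$dot_radius, sep = "|")
  G <- rowsum(A, key)
  cnt <- as.vector(table(key)[rownames(G)])
  G <- G / cnt
  kk <- do.call(rbind, strsplit(rownames(G), "|", fixed = TRUE))
  gi <- data.frame(mouse = as.numeric(kk[, 1]), speed = as.numeric(kk[, 2]),
                   direction = kk[, 3], contrast = as.numeric(kk[, 4]),
                   dot_radius = as.numeric(kk[, 5]))
  info <- list()
  curves <- list()
  for (m in unique(gi$mouse)) {
    for (co in unique(gi$contrast[gi$mouse == m])) {
      for (dr in unique(gi$dot_radius[gi$mouse == m & gi$contrast == co])) {
        sel <- gi$mouse == m & gi$contrast == co & gi$dot_radius == dr
        zsel <- sel & gi$speed == 0
        if (!any(zsel)) stop("zero-speed condition missing", call. = FALSE)
        z <- colSums(G[zsel, , drop = FALSE] * cnt[zsel]) / sum(cnt[zsel])
        for (sp in sort(unique(gi$speed[sel]))) {
          if (sp == 0) {
            cv <- numeric(ncol(G))  # pooled-pair convention: folds to zero
          } else {
            r <- G[sel & gi$speed == sp & gi$direction == "right", ]
            l <- G[sel & gi$speed == sp & gi$direction == "left", ]
            if (!is.matrix(r) && !is.matrix(l) &&
                length(r) == ncol(G) && length(l) == ncol(G)) {
              cv <- ((r - z) - (l - z)) / 2
            } else {
              stop(sprintf("missing left/right pair member at speed %g", sp),
                   call. = FALSE)
            }
          }
          info[[length(info) + 1L]] <- data.frame(
            mouse = m, speed = sp, contrast = co, dot_radius = dr)
          curves[[length(curves) + 1L]] <- cv
        }
      }
    }
  }
  structure(
    list(info = do.call(rbind, info), curves = do.call(rbind, curves),
         t = seq(-pre, post - 1) / fs, fs = fs),
    class = "olr_curves"
  )
}

#' Across-mouse normalization of an OLR table
#'
#' To prevent the strongest responders from dominating condition means, each
#' mouse's OLR-vs-condition vector is z-scored and scaled back to population
#' units: `norm = z * sd_pop + mean_pop`. The population location and scale
#' are the across-mouse means of the per-mouse curve means and SDs
#' (population, i.e. divide-by-n, denominators), so after normalization every
#' mouse's curve has exactly the same mean and SD, the pooled mean of the
#' table is unchanged, and a homogeneous cohort passes through untouched.
#' Amplitude differences between mice are thereby removed without inflating
#' the modulation of the population-mean curve.
#'
#' @param olr_table An [fold_olr_table()] result.
#' @return The table with an added `olr_norm` column.
#' @export
normalize_across_mice <- function(olr_table) {
  stopifnot(is.data.frame(olr_table), all(c("mouse", "olr") %in%
                                            names(olr_table)))
  mice <- unique(olr_table$mouse)
  if (length(mice) < 2L) stop("need at least 2 mice", call. = FALSE)
  ms <- vapply(mice, function(m) mean(olr_table$olr[olr_table$mouse == m]),
               numeric(1))
  ss <- vapply(mice, function(m) psd(olr_table$olr[olr_table$mouse == m]),
               numeric(1))
  if (any(vapply(mice, function(m)
    sum(olr_table$mouse == m), integer(1)) < 2L)) {
    stop("need at least 2 conditions per mouse", call. = FALSE)
  }
  if (any(ss == 0)) {
    stop("degenerate: a mouse has zero variance across conditions",
         call. = FALSE)
  }
  mean_pop <- mean(ms)
  sd_pop <- mean(ss)
  idx <- match(olr_table$mouse, mice)
  z <- (olr_table$olr - ms[idx]) / ss[idx]
  olr_table$olr_norm <- z * sd_pop + mean_pop
  olr_table
}

#' One-sample t-test of per-mouse OLRs against zero
#'
#' Two-sided test at level `alpha`; in the assay's figures a non-significant
#' condition is drawn with an open marker. Zero-variance input is flagged
#' degenerate (p is 1 when the common value is 0, otherwise 0).
#'
#' @param x Per-mouse OLR values for one condition (>= 2 values).
#' @param alpha Significance level.
#' @return List with `statistic`, `p.value`, `significant`, `degenerate`.
#' @export
ttest_vs_zero <- function(x, alpha = 0.05) {
  if (length(x) < 2L) stop("need at least 2 mice", call. = FALSE)
  if (stats::sd(x) == 0) {
    p <- if (mean(x) == 0) 1 else 0
    return(list(statistic = if (mean(x) == 0) 0 else Inf, p.value = p,
                significant = p < alpha, degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = 0)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Condition summary: across-mouse mean, SEM and t-test
#'
#' The mouse is the unit of replication: for every condition the mean, the
#' standard error of the mean across the cohort's per-mouse OLRs, and a
#' two-sided one-sample t-test against zero are reported.
#'
#' @param olr_table A (normalized) `olr_table`.
#' @param value Column to summarize, `"olr_norm"` (default if present) or
#'   `"olr"`.
#' @param alpha Level of the t-test.
#' @return An `olr_summary` data frame: `speed`, `contrast`, `dot_radius`,
#'   `n`, `mean`, `sem`, `p.value`, `significant`.
#' @export
condition_summary <- function(olr_table, value = NULL, alpha = 0.05) {
  if (is.null(value)) {
    value <- if ("olr_norm" %in% names(olr_table)) "olr_norm" else "olr"
  }
  stopifnot(value %in% names(olr_table))
  key <- unique(olr_table[c("speed", "contrast", "dot_radius")])
  key <- key[order(key$contrast, key$dot_radius, key$speed), , drop = FALSE]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- olr_table$speed == key$speed[i] &
      olr_table$contrast == key$contrast[i] &
      olr_table$dot_radius == key$dot_radius[i]
    x <- olr_table[[value]][sel]
    if (length(x) < 2L) stop("need at least 2 mice per condition",
                             call. = FALSE)
    tt <- ttest_vs_zero(x, alpha)
    data.frame(speed = key$speed[i], contrast = key$contrast[i],
               dot_radius = key$dot_radius[i], n = length(x),
               mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
               p.value = tt$p.value, significant = tt$significant)
  })
  structure(do.call(rbind, rows), class = c("olr_summary", "data.frame"))
}

#' OLR gain
#'
#' The OLR divided by the stimulus speed that evoked it; a gain of 1 means
#' the mouse's turning fully matches the stimulus. Undefined at zero speed
#' (such conditions are excluded from gain tables).
#'
#' @param olr OLR in deg/s (vectorized).
#' @param speed Stimulus speed in deg/s, > 0.
#' @return Dimensionless gain.
#' @examples
#' compute_gain(29.5, 36.4)  # 0.81
#' @export
compute_gain <- function(olr, speed) {
  if (any(speed <= 0)) stop("gain is undefined at zero speed", call. = FALSE)
  olr / speed
}

#' Add a gain column to an OLR table
#'
#' @param olr_table An `olr_table` (nonzero speeds only).
#' @return The table with `gain` (and `gain_norm` when `olr_norm` exists).
#' @export
add_gain <- function(olr_table) {
  olr_table$gain <- compute_gain(olr_table$olr, olr_table$speed)
  if ("olr_norm" %in% names(olr_table)) {
    olr_table$gain_norm <- compute_gain(olr_table$olr_norm, olr_table$speed)
  }
  olr_table
}
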