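# subset an olr_trials object by row index, keeping metadata consistent
subset_trials <- function(trials, rows) {
  structure(list(meta = trials$meta[rows, , drop = FALSE],
                 yaw = trials$yaw[rows, , drop = FALSE], fs = trials$fs,
                 mice = trials$mice, tuning = trials$tuning,
                 experiment = trials$experiment),
            class = "olr_trials")
}

factor_var <- function(experiment) {
  switch(experiment, speed = NULL, contrast = "contrast",
         dotsize = "dot_radius")
}

#' Full OLR analysis of one experiment
#'
#' Runs the complete reflex-extraction and fitting pipeline on a trial
#' dataset: per-trial OLR scalars (boxcar smoothing, baseline subtraction,
#' 1-2 s window), zero-speed correction and direction folding, across-mouse
#' normalization, condition summary with SEMs and t-tests, weighted
#' polynomial fit with stepwise model selection, and a bootstrap peak
#' estimate; then the same fitting applied to the OLR gain.
#'
#' For the speed experiment the OLR-vs-speed curve is fitted over a
#' line/quadratic/cubic ladder (the quadratic is the assay's reference
#' model) and the gain curve over a ladder up to quartic; the bootstrap
#' refits use the selected orders. For the surface experiments the ladder is
#' poly22 / poly23 (or poly32) / poly33.
#'
#' @param trials An `olr_trials` dataset.
#' @param B Bootstrap resamples (200 by default).
#' @param seed Optional seed for the bootstrap.
#' @param alpha Level for model selection and t-tests.
#' @return An `olr_analysis` list: `table` (normalized per-mouse OLR/gain
#'   table), `summary` and `gain_summary` (condition summaries), `olr`
#'   and `gain` sublists each with `selection` (trail), `fit`, `peak`,
#'   `boot`.
#' @export
run_olr_pipeline <- function(trials, B = 200, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(trials, "olr_trials"))
  tab <- normalize_across_mice(fold_olr_table(compute_trial_olrs(trials)))
  tab <- add_gain(tab)
  summ <- condition_summary(tab, "olr_norm", alpha)
  gsumm <- condition_summary(tab, "gain_norm", alpha)
  fv <- factor_var(trials$experiment)
  analyse <- function(sm, value_boot, ladder, boot_deg_or_order) {
    if (is.null(fv)) {
      sel <- select_model(sm$speed, sm$mean, sm$sem, ladder, alpha = alpha)
      bt <- bootstrap_peak(tab, "speed", value_boot,
                           degree = boot_deg_or_order, B = B, seed = seed)
    } else {
      sel <- select_model(sm[[fv]], sm$mean, sm$sem, ladder, x2 = sm$speed,
                          alpha = alpha)
      bt <- bootstrap_peak(tab, c(fv, "speed"), value_boot,
                           order = boot_deg_or_order, B = B, seed = seed)
    }
    list(selection = sel$trail, fit = sel$fit,
         peak = peak_of_fit(sel$fit), boot = bt)
  }
  if (is.null(fv)) {
    olr_part <- analyse(summ, "olr_norm", c(1, 2, 3), 2)
    gain_part <- analyse(gsumm, "gain_norm", c(1, 2, 3, 4), 3)
  } else {
    ladder <- list(c(2, 2), c(2, 3), c(3, 3))
    olr_part <- analyse(summ, "olr_norm", ladder, c(2, 3))
    gain_part <- analyse(gsumm, "gain_norm", ladder, c(2, 3))
  }
  structure(list(experiment = trials$experiment, table = tab,
                 summary = summ, gain_summary = gsumm,
                 olr = olr_part, gain = gain_part),
            class = "olr_analysis")
}

#' @export
print.olr_analysis <- function(x, ...) {
  cat(sprintf("OLR analysis (%s experiment)\n", x$experiment))
  cat(sprintf("  conditions: %d, mice: %d\n", nrow(x$summary),
              length(unique(x$table$mouse))))
  cat("  OLR peak (bootstrap):\n")
  for (v in names(x$olr$boot$mean)) {
    cat(sprintf("    %-10s %.4g (SD %.3g)\n", v, x$olr$boot$mean[[v]],
                x$olr$boot$sd[[v]]))
  }
  cat("  Gain peak (bootstrap):\n")
  for (v in names(x$gain$boot$mean)) {
    cat(sprintf("    %-10s %.4g (SD %.3g)\n", v, x$gain$boot$mean[[v]],
                x$gain$boot$sd[[v]]))
  }
  invisible(x)
}

#' Consistency analysis by splitting a dataset
#'
#' Re-analyses a speed-experiment dataset in two halves to probe the
#' stability of the reflex: either the first versus second half of every
#' session's trial sequence (`"within_session"`, fatigue / habituation
#' within the 40-minute session) or each mouse's sessions before versus from
#' the middle session onward (`"across_sessions"`, drift of the reflex over
#' the testing period). Each half goes through the full pipeline
#' independently and the bootstrap peak intervals are compared per axis.
#'
#' @param trials An `olr_trials` dataset with at least two sessions for the
#'   across-session split.
#' @param split `"within_session"` or `"across_sessions"`.
#' @param B,seed,alpha As in [run_olr_pipeline()].
#' @return An `olr_split` list: `halves` (two `olr_analysis` results, named
#'   `early` and `late`), `overlap` (logical per peak axis: do the bootstrap
#'   CIs overlap?), `amplitude_ratio` (mean late/early OLR over conditions).
#' @export
session_split_analysis <- function(trials,
                                   split = c("within_session",
                                             "across_sessions"),
                                   B = 200, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(trials, "olr_trials"))
  split <- match.arg(split)
  meta <- trials$meta
  if (split == "within_session") {
    early <- rep(FALSE, nrow(meta))
    for (m in unique(meta$mouse)) {
      for (s in unique(meta$session[meta$mouse == m])) {
        sel <- which(meta$mouse == m & meta$session == s)
        cut <- meta$trial[sel] <= max(meta$trial[sel]) / 2
        early[sel] <- cut
      }
    }
  } else {
    early <- rep(FALSE, nrow(meta))
    for (m in unique(meta$mouse)) {
      sel <- meta$mouse == m
      ses <- sort(unique(meta$session[sel]))
      if (length(ses) < 2L) {
        stop("across-session split needs at least two sessions per mouse",
             call. = FALSE)
      }
      mid <- ses[ceiling((length(ses) + 1) / 2)]
      early[sel] <- meta$session[sel] < mid
    }
  }
  halves <- list(
    early = run_olr_pipeline(subset_trials(trials, which(early)), B, seed,
                             alpha),
    late = run_olr_pipeline(subset_trials(trials, which(!early)), B, seed,
                            alpha)
  )
  ax <- setdiff(rownames(halves$early$olr$boot$ci), "height")
  overlap <- vapply(ax, function(v) {
    a <- halves$early$olr$boot$ci[v, ]
    b <- halves$late$olr$boot$ci[v, ]
    a["lower"] <= b["upper"] && b["lower"] <= a["upper"]
  }, logical(1))
  m_early <- halves$early$summary$mean
  m_late <- halves$late$summary$mean
  structure(list(split = split, halves = halves, overlap = overlap,
                 amplitude_ratio = mean(m_late) / mean(m_early)),
            class = "olr_split")
}

#' @export
print.olr_split <- function(x, ...) {
  cat(sprintf("Session-split consistency analysis (%s)\n", x$split))
  cat(sprintf("  late/early OLR amplitude ratio: %.3g\n", x$amplitude_ratio))
  for (v in names(x$overlap)) {
    cat(sprintf("  peak %s CIs overlap: %s\n", v, x$overlap[[v]]))
  }
  invisible(x)
}
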