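# exponent tables ----------------------------------------------------------

# 1D polynomial of given degree: exponents 0..degree
poly_terms_1d <- function(degree) {
  data.frame(i = 0:degree)
}

#' Exponent table of a polyMN surface
#'
#' A `poly(m, n)` surface in `(x1, x2)` contains the monomials
#' `x1^i * x2^j` with `i <= m`, `j <= n` and `i + j <= max(m, n)`. This term
#' rule gives 6 parameters for poly22, 9 for poly23 and poly32, and 10 for
#' poly33 — the parameter counts used in the assay's model comparisons.
#'
#' @param m,n Maximum exponents of the first and second variable.
#' @return Data frame of exponent pairs `i`, `j`.
#' @export
surface_terms <- function(m, n) {
  g <- expand.grid(i = 0:m, j = 0:n, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$i + g$j <= max(m, n), , drop = FALSE]
  g <- g[order(g$i + g$j, g$i), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# design matrix from an exponent table; X is a matrix with one column per
# monomial, data a list/data frame with the predictor columns
design_matrix <- function(terms, data, xvars) {
  n <- length(data[[xvars[1]]])
  X <- matrix(0, n, nrow(terms))
  cn <- character(nrow(terms))
  for (k in seq_len(nrow(terms))) {
    if (length(xvars) == 1L) {
      X[, k] <- data[[xvars[1]]]^terms$i[k]
      cn[k] <- if (terms$i[k] == 0) "(Intercept)" else
        sprintf("%s^%d", xvars[1], terms$i[k])
    } else {
      X[, k] <- data[[xvars[1]]]^terms$i[k] * data[[xvars[2]]]^terms$j[k]
      cn[k] <- if (terms$i[k] == 0 && terms$j[k] == 0) "(Intercept)" else
        sprintf("%s^%d.%s^%d", xvars[1], terms$i[k], xvars[2], terms$j[k])
    }
  }
  colnames(X) <- cn
  X
}

# core weighted least squares: minimize sum((w * r)^2) with w = 1/se,
# i.e. regression weights 1/se^2
olr_wls <- function(X, y, se, terms, xvars, data) {
  if (any(se <= 0) || any(!is.finite(se))) {
    stop("all standard errors must be positive and finite", call. = FALSE)
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more parameters than data points", call. = FALSE)
  w2 <- 1 / se^2
  fit <- stats::lm.wfit(X, y, w2)
  if (fit$rank < p) stop("singular design matrix", call. = FALSE)
  res <- y - drop(X %*% fit$coefficients)
  rss_w <- sum(w2 * res^2)
  ybar_w <- sum(w2 * y) / sum(w2)
  tss_w <- sum(w2 * (y - ybar_w)^2)
  structure(
    list(coefficients = fit$coefficients, terms = terms, xvars = xvars,
         data = data, y = y, se = se, fitted.values = drop(X %*% fit$coefficients),
         residuals = res, rss_w = rss_w, tss_w = tss_w,
         r.squared = 1 - rss_w / tss_w, n = n, p = p,
         xrange = lapply(xvars, function(v) range(data[[v]]))),
    class = "olr_fit"
  )
}

#' Inverse-SE-weighted polynomial curve fit
#'
#' Fits `y ~ poly(x, degree)` by linear least squares with the residuals
#' weighted linearly by the inverse of the standard errors: the objective is
#' `sum((r / se)^2)`. This is the assay's tuning-curve model: `x` is the
#' condition value (e.g. stimulus speed), `y` the across-mouse mean OLR per
#' condition and `se` its SEM, so imprecise conditions count less.
#'
#' @param x Condition values.
#' @param y Mean responses.
#' @param se Standard errors of `y`, all > 0.
#' @param degree Polynomial degree (n_points must exceed degree + 1).
#' @return An `olr_fit` object with `coefficients` (increasing powers),
#'   weighted residual sum of squares `rss_w`, weighted `r.squared` (about
#'   the weighted mean), `n`, `p`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `anova` (nested F-tests).
#' @seealso [fit_surface_weighted()], [nested_f_test()], [peak_of_fit()]
#' @export
fit_poly_weighted <- function(x, y, se, degree) {
  stopifnot_scalar(degree, "degree", positive = TRUE)
  stopifnot(length(x) == length(y), length(se) == length(y))
  terms <- poly_terms_1d(as.integer(degree))
  data <- list(x = as.numeric(x))
  olr_wls(design_matrix(terms, data, "x"), as.numeric(y), as.numeric(se),
          terms, "x", data)
}

#' Inverse-SE-weighted polynomial surface fit
#'
#' Two-factor analogue of [fit_poly_weighted()] for tuning surfaces over
#' (contrast or dot size) x speed, using the polyMN term rule of
#' [surface_terms()].
#'
#' @param x1,x2 Condition values of the two factors (e.g. contrast and
#'   speed).
#' @param y,se Mean responses and their standard errors.
#' @param order Length-2 integer vector `c(m, n)`: maximum exponents for
#'   `x1` and `x2`.
#' @return An `olr_fit` object (see [fit_poly_weighted()]).
#' @export
fit_surface_weighted <- function(x1, x2, y, se, order) {
  stopifnot(length(order) == 2L, length(x1) == length(y),
            length(x2) == length(y), length(se) == length(y))
  terms <- surface_terms(order[1], order[2])
  data <- list(x1 = as.numeric(x1), x2 = as.numeric(x2))
  fit <- olr_wls(design_matrix(terms, data, c("x1", "x2")), as.numeric(y),
                 as.numeric(se), terms, c("x1", "x2"), data)
  fit$order <- as.integer(order)
  fit
}

# methods -------------------------------------------------------------------

#' @export
print.olr_fit <- function(x, ...) {
  if (length(x$xvars) == 1L) {
    cat(sprintf("Weighted polynomial fit, degree %d (%d parameters)\n",
                max(x$terms$i), x$p))
  } else {
    cat(sprintf("Weighted polynomial surface poly%d%d (%d parameters)\n",
                x$order[1], x$order[2], x$p))
  }
  cat(sprintf("n = %d, weighted RSS = %.4g, weighted R^2 = %.4f\n",
              x$n, x$rss_w, x$r.squared))
  cat("Coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.olr_fit <- function(object, ...) object$coefficients

#' @export
fitted.olr_fit <- function(object, ...) object$fitted.values

#' @export
residuals.olr_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  if (type == "raw") object$residuals else object$residuals / object$se
}

#' Predict from a weighted polynomial fit
#'
#' @param object An `olr_fit`.
#' @param newdata For 1D fits a numeric vector or a data frame with column
#'   `x`; for surfaces a data frame (or list) with columns `x1`, `x2`.
#'   Omitted: the fitted values.
#' @param ... Unused.
#' @return Predicted response values.
#' @export
predict.olr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (length(object$xvars) == 1L && is.numeric(newdata)) {
    newdata <- list(x = newdata)
  }
  X <- design_matrix(object$terms, newdata, object$xvars)
  drop(X %*% object$coefficients)
}

#' @export
summary.olr_fit <- function(object, ...) {
  w2 <- 1 / object$se^2
  X <- design_matrix(object$terms, object$data, object$xvars)
  XtWX <- crossprod(X * sqrt(w2))
  sigma2 <- object$rss_w / (object$n - object$p)
  vc <- sigma2 * solve(XtWX)
  se_coef <- sqrt(diag(vc))
  tval <- object$coefficients / se_coef
  pval <- 2 * stats::pt(abs(tval), object$n - object$p, lower.tail = FALSE)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se_coef,
               `t value` = tval, `Pr(>|t|)` = pval)
  structure(list(coefficients = tab, r.squared = object$r.squared,
                 rss_w = object$rss_w, n = object$n, p = object$p,
                 sigma = sqrt(sigma2), fit = object),
            class = "summary.olr_fit")
}

#' @export
print.summary.olr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Residual weighted SD: %.4g on %d degrees of freedom\n",
              x$sigma, x$n - x$p))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Plot a weighted polynomial fit
#'
#' 1D fits: data with error bars (`+- se`) and the fitted curve. Surfaces:
#' a filled contour of the fitted surface with the data locations.
#'
#' @param x An `olr_fit`.
#' @param n_grid Curve/contour resolution.
#' @param xlab,ylab,main Axis labels.
#' @param ... Passed to the underlying plot call.
#' @return The fit, invisibly.
#' @export
plot.olr_fit <- function(x, n_grid = 200, xlab = NULL, ylab = "OLR (deg/s)",
                         main = NULL, ...) {
  if (length(x$xvars) == 1L) {
    xs <- x$data$x
    xx <- seq(min(xs), max(xs), length.out = n_grid)
    yy <- predict(x, xx)
    ylim <- range(x$y - x$se, x$y + x$se, yy)
    graphics::plot(xs, x$y, pch = 16, ylim = ylim,
                   xlab = if (is.null(xlab)) "condition" else xlab,
                   ylab = ylab, main = main, ...)
    graphics::arrows(xs, x$y - x$se, xs, x$y + x$se, angle = 90, code = 3,
                     length = 0.03)
    graphics::lines(xx, yy, col = "firebrick", lwd = 2)
  } else {
    g1 <- seq(x$xrange[[1]][1], x$xrange[[1]][2], length.out = n_grid)
    g2 <- seq(x$xrange[[2]][1], x$xrange[[2]][2], length.out = n_grid)
    z <- outer(g1, g2, function(a, b) predict(x, list(x1 = a, x2 = b)))
    graphics::filled.contour(
      g1, g2, z, xlab = if (is.null(xlab)) "factor" else xlab,
      ylab = "speed (deg/s)", main = main,
      plot.axes = {
        graphics::axis(1); graphics::axis(2)
        graphics::points(x$data$x1, x$data$x2, pch = 3)
      }, ...)
  }
  invisible(x)
}

# model comparison ----------------------------------------------------------

same_fit_data <- function(small, large) {
  isTRUE(all.equal(small$y, large$y)) &&
    isTRUE(all.equal(small$se, large$se)) &&
    identical(small$xvars, large$xvars) &&
    isTRUE(all.equal(small$data, large$data))
}

terms_nested <- function(small, large) {
  key <- function(tm) {
    if ("j" %in% names(tm)) paste(tm$i, tm$j) else paste(tm$i)
  }
  all(key(small$terms) %in% key(large$terms)) &&
    nrow(small$terms) < nrow(large$terms)
}

#' Nested F-test between two weighted polynomial fits
#'
#' Compares a smaller model against a larger one whose monomials are a
#' superset, on identical data and weights:
#' `F = ((RSS_s - RSS_l) / dp) / (RSS_l / (n - p_l))`, reported with
#' degrees of freedom `(dp, n - p_l)` and a p-value from the F distribution.
#' Both residual sums of squares are the weighted ones, consistently with
#' the weighted fits being compared.
#'
#' @param small,large `olr_fit` objects; `small` must be nested in `large`.
#' @param alpha Level used to label the preferred model.
#' @return An `olr_ftest`: list with `statistic`, `df1`, `df2`, `p.value`,
#'   `preferred` (`"small"` or `"large"`).
#' @export
nested_f_test <- function(small, large, alpha = 0.05) {
  stopifnot(inherits(small, "olr_fit"), inherits(large, "olr_fit"))
  if (!same_fit_data(small, large)) {
    stop("models were not fitted to the same data and weights", call. = FALSE)
  }
  if (!terms_nested(small, large)) {
    stop("models are not nested", call. = FALSE)
  }
  df1 <- large$p - small$p
  df2 <- large$n - large$p
  num <- (small$rss_w - large$rss_w) / df1
  den <- large$rss_w / df2
  # an exactly-interpolating large model: F is 0 when the small model is
  # just as exact, infinite otherwise
  Fstat <- if (den <= 0) {
    if (num <= 1e-12) 0 else Inf
  } else {
    max(0, num / den)
  }
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = Fstat, df1 = df1, df2 = df2, p.value = p,
                 preferred = if (p < alpha) "large" else "small",
                 alpha = alpha),
            class = "olr_ftest")
}

#' @export
print.olr_ftest <- function(x, ...) {
  cat(sprintf("Nested F-test: F(%d,%d) = %.4g, p = %.4g -> prefer %s model\n",
              x$df1, x$df2, x$statistic, x$p.value, x$preferred))
  invisible(x)
}

#' @export
anova.olr_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2L) stop("supply at least two fits to compare",
                              call. = FALSE)
  rows <- lapply(seq_along(fits)[-1], function(k) {
    ft <- nested_f_test(fits[[k - 1]], fits[[k]])
    data.frame(p_small = fits[[k - 1]]$p, p_large = fits[[k]]$p,
               F = ft$statistic, df1 = ft$df1, df2 = ft$df2,
               p.value = ft$p.value)
  })
  do.call(rbind, rows)
}

#' Stepwise-up model selection over a nested ladder
#'
#' Walks up an ordered ladder of nested candidate models (e.g. line,
#' quadratic, cubic), accepting the larger model whenever its nested F-test
#' against the current model has `p < alpha`, and stopping at the first
#' rejection.
#'
#' @param x,y,se Data as in [fit_poly_weighted()]; for surfaces also give
#'   `x2` and make `ladder` a list of `c(m, n)` orders.
#' @param ladder Increasing degrees (1D, numeric vector) or a list of
#'   surface orders.
#' @param x2 Second factor values for surface ladders.
#' @param alpha Acceptance level.
#' @return List with `fit` (the selected `olr_fit`) and `trail`, a data
#'   frame of the tests performed.
#' @export
select_model <- function(x, y, se, ladder, x2 = NULL, alpha = 0.05) {
  fit_one <- function(spec) {
    if (is.null(x2)) fit_poly_weighted(x, y, se, spec)
    else fit_surface_weighted(x, x2, y, se, spec)
  }
  specs <- if (is.list(ladder)) ladder else as.list(ladder)
  if (length(specs) == 0L) stop("empty ladder", call. = FALSE)
  cur <- fit_one(specs[[1]])
  lab <- function(spec) if (length(spec) == 2L)
    sprintf("poly%d%d", spec[1], spec[2]) else sprintf("degree %d", spec)
  trail <- list()
  if (length(specs) > 1L) {
    for (k in seq_along(specs)[-1]) {
      cand <- fit_one(specs[[k]])
      ft <- nested_f_test(cur, cand, alpha)
      trail[[length(trail) + 1L]] <- data.frame(
        small = lab(specs[[k - 1]]), large = lab(specs[[k]]),
        F = ft$statistic, df1 = ft$df1, df2 = ft$df2, p.value = ft$p.value,
        accepted = ft$preferred == "large")
      if (ft$preferred == "large") cur <- cand else break
    }
  }
  list(fit = cur,
       trail = if (length(trail)) do.call(rbind, trail) else
         data.frame(small = character(), large = character(), F = numeric(),
                    df1 = integer(), df2 = integer(), p.value = numeric(),
                    accepted = logical()))
}

# peak finding --------------------------------------------------------------

#' Peak of a fitted tuning curve or surface
#'
#' Maximizes the fitted polynomial over the closed tested domain. 1D fits
#' are solved analytically (real roots of the derivative plus the domain
#' endpoints); surfaces by a dense grid search refined with bounded
#' quasi-Newton optimization. A maximum attained on the domain boundary
#' (including the degenerate upward-curved quadratic) is flagged.
#'
#' @param fit An `olr_fit`.
#' @param lower,upper Domain bounds per predictor; default: the range of the
#'   fitted data.
#' @param n_grid Grid resolution per axis for the surface search.
#' @return List of class `olr_peak` with `location` (named vector), `height`
#'   and `boundary` (logical).
#' @export
peak_of_fit <- function(fit, lower = NULL, upper = NULL, n_grid = 201) {
  stopifnot(inherits(fit, "olr_fit"))
  d <- length(fit$xvars)
  if (is.null(lower)) lower <- vapply(fit$xrange, `[`, numeric(1), 1)
  if (is.null(upper)) upper <- vapply(fit$xrange, `[`, numeric(1), 2)
  lower <- rep_len(lower, d)
  upper <- rep_len(upper, d)
  if (d == 1L) {
    co <- fit$coefficients  # increasing powers
    deg <- length(co) - 1L
    cand <- c(lower, upper)
    if (deg >= 2L) {
      dco <- co[-1] * seq_len(deg)
      rt <- polyroot(dco)
      re <- Re(rt[abs(Im(rt)) < 1e-8])
      cand <- c(cand, re[re > lower & re < upper])
    }
    vals <- vapply(cand, function(z) sum(co * z^(0:deg)), numeric(1))
    best <- which.max(vals)
    loc <- cand[best]
    tol <- 1e-8 * (upper - lower)
    boundary <- loc <= lower + tol || loc >= upper - tol
    loc <- stats::setNames(loc, fit$xvars)
    return(structure(list(location = loc, height = vals[best],
                          boundary = boundary), class = "olr_peak"))
  }
  g1 <- seq(lower[1], upper[1], length.out = n_grid)
  g2 <- seq(lower[2], upper[2], length.out = n_grid)
  z <- outer(g1, g2, function(a, b) predict(fit, list(x1 = a, x2 = b)))
  idx <- arrayInd(which.max(z), dim(z))
  start <- c(g1[idx[1]], g2[idx[2]])
  opt <- stats::optim(start, function(p) predict(fit, list(x1 = p[1], x2 = p[2])),
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(fnscale = -1))
  tol <- 1e-6 * (upper - lower)
  boundary <- any(opt$par <= lower + tol | opt$par >= upper - tol)
  structure(list(location = stats::setNames(opt$par, fit$xvars),
                 height = opt$value, boundary = boundary),
            class = "olr_peak")
}

#' @export
print.olr_peak <- function(x, ...) {
  loc <- paste(sprintf("%s = %.3g", names(x$location), x$location),
               collapse = ", ")
  cat(sprintf("Peak at %s, height %.3g%s\n", loc, x$height,
              if (x$boundary) " (on domain boundary)" else ""))
  invisible(x)
}

# bootstrap -----------------------------------------------------------------

#' 95\% normal-theory ellipse from a 2x2 covariance
#'
#' @param center Length-2 center.
#' @param sigma 2x2 covariance matrix.
#' @param level Coverage level.
#' @param n Number of polygon points.
#' @return Matrix (n x 2) of ellipse boundary points.
#' @export
covariance_ellipse <- function(center, sigma, level = 0.95, n = 100) {
  r <- sqrt(stats::qchisq(level, df = 2))
  th <- seq(0, 2 * pi, length.out = n)
  circ <- r * cbind(cos(th), sin(th))
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  pts <- circ %*% (t(ev$vectors) * sqrt(lam))
  sweep(pts, 2, center, "+")
}

#' Bootstrap distribution of a tuning peak
#'
#' Resamples the mouse x condition OLR points with replacement (the
#' individual point is the resampling unit), recomputes the condition means
#' and SEMs of each resample, refits the weighted polynomial and records the
#' peak of the refitted model; by default 200 resamples. A resample in which
#' some condition has fewer than two points (so its SEM is undefined) is
#' redrawn and counted.
#'
#' @param points Data frame of per-mouse condition points: must contain the
#'   predictor column(s) and the response column `y`.
#' @param xvars Predictor column name(s): one for a curve, two for a surface
#'   (factor first, speed second).
#' @param y Response column name (e.g. `"olr_norm"` or `"gain_norm"`).
#' @param degree Curve degree (1D) — or —
#' @param order surface order `c(m, n)`.
#' @param lower,upper Peak search domain (default: range of each predictor).
#' @param B Number of bootstrap resamples.
#' @param seed Optional seed.
#' @param level Interval level.
#' @return An `olr_peak_boot`: list with `replicates` (B rows of peak
#'   locations/heights), `mean`, `sd`, `ci` (percentile interval per axis
#'   and for the height), `cov` and `ellipse` (2D only), `n_points`,
#'   `n_redraws`, `n_boundary`.
#' @export
bootstrap_peak <- function(points, xvars, y = "olr_norm", degree = NULL,
                           order = NULL, lower = NULL, upper = NULL,
                           B = 200, seed = NULL, level = 0.95) {
  stopifnot(is.data.frame(points), all(xvars %in% names(points)),
            y %in% names(points))
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  if (is.null(degree) && is.null(order)) {
    stop("give `degree` (curve) or `order` (surface)", call. = FALSE)
  }
  d <- length(xvars)
  if (is.null(lower)) lower <- vapply(xvars, function(v) min(points[[v]]),
                                      numeric(1))
  if (is.null(upper)) upper <- vapply(xvars, function(v) max(points[[v]]),
                                      numeric(1))
  cond_key <- do.call(paste, c(points[xvars], sep = "|"))
  all_conds <- unique(cond_key)
  n <- nrow(points)
  fit_resample <- function(idx) {
    k <- cond_key[idx]
    tb <- table(k)
    if (length(tb) < length(all_conds)) return(NULL)  # condition absent
    yv <- points[[y]][idx]
    mu <- tapply(yv, k, mean)
    sem <- tapply(yv, k, stats::sd) / sqrt(tb[names(mu)])
    # conditions drawn with a single point (SEM undefined) or with identical
    # points (SEM zero, e.g. noise-free data) get the smallest positive SEM
    # of the resample as floor -- equal weights if none exists
    bad <- is.na(sem) | sem == 0
    if (any(bad)) {
      sem[bad] <- if (all(bad)) 1 else min(sem[!bad])
    }
    cv <- do.call(rbind, strsplit(names(mu), "|", fixed = TRUE))
    if (d == 1L) {
      fit <- fit_poly_weighted(as.numeric(cv[, 1]), as.numeric(mu),
                               as.numeric(sem), degree)
    } else {
      fit <- fit_surface_weighted(as.numeric(cv[, 1]), as.numeric(cv[, 2]),
                                  as.numeric(mu), as.numeric(sem), order)
    }
    peak_of_fit(fit, lower, upper)
  }
  with_seed(seed, {
    reps <- matrix(NA_real_, B, d + 1)
    n_redraws <- 0L
    n_boundary <- 0L
    for (b in seq_len(B)) {
      pk <- NULL
      while (is.null(pk)) {
        pk <- fit_resample(sample.int(n, n, replace = TRUE))
        if (is.null(pk)) n_redraws <- n_redraws + 1L
        if (n_redraws > 100L * B) {
          stop("too many degenerate bootstrap resamples", call. = FALSE)
        }
      }
      if (pk$boundary) n_boundary <- n_boundary + 1L
      reps[b, ] <- c(pk$location, pk$height)
    }
    colnames(reps) <- c(xvars, "height")
    reps <- as.data.frame(reps)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- t(vapply(reps, stats::quantile, numeric(2), probs = qs))
    colnames(ci) <- c("lower", "upper")
    out <- list(replicates = reps,
                mean = vapply(reps, mean, numeric(1)),
                sd = vapply(reps, stats::sd, numeric(1)),
                ci = ci, level = level, B = B,
                n_points = n, n_redraws = n_redraws, n_boundary = n_boundary)
    if (d == 2L) {
      out$cov <- stats::cov(reps[, 1:2])
      out$ellipse <- covariance_ellipse(colMeans(reps[, 1:2]),
                                        as.matrix(out$cov), level)
    }
    structure(out, class = "olr_peak_boot")
  })
}

#' @export
print.olr_peak_boot <- function(x, ...) {
  cat(sprintf("Bootstrap peak estimate (B = %d, %d points, %d redraws)\n",
              x$B, x$n_points, x$n_redraws))
  for (v in names(x$mean)) {
    cat(sprintf("  %-8s mean %.4g  SD %.3g  %g%%-CI [%.4g, %.4g]\n", v,
                x$mean[[v]], x$sd[[v]], 100 * x$level,
                x$ci[v, "lower"], x$ci[v, "upper"]))
  }
  if (x$n_boundary > 0) {
    cat(sprintf("  %d replicate peak(s) on the domain boundary\n",
                x$n_boundary))
  }
  invisible(x)
}
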