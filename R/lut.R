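#' Build a projector lookup table
#'
#' The dome mapping is calibrated by projecting a raster of sample dots
#' evenly spaced in projector pixel coordinates (by default 20 x 10 = 200
#' nodes) and measuring the azimuth and elevation of each on the dome. The
#' resulting table maps `(azi, ele)` back to `(x, y)` pixels by per-cell
#' bilinear interpolation, see [project()].
#'
#' @param node_measurements Data frame with columns `x`, `y` (projector
#'   pixels) and `azi`, `ele` (degrees), in row-major grid order: `y` varies
#'   slowest, `x` fastest, both increasing.
#' @return An object of class `projection_lut`.
#' @details The measurements must form a complete rectangular grid in
#'   `(x, y)` and the measured angles must be strictly monotone along the
#'   grid axes (azimuth along `x` within each row, elevation along `y` within
#'   each column); violations raise a format error, which catches shuffled or
#'   corrupted calibration files.
#' @export
build_lut <- function(node_measurements) {
  m <- as.data.frame(node_measurements)
  need <- c("x", "y", "azi", "ele")
  if (!all(need %in% names(m))) {
    stop("LUT format error: need columns x, y, azi, ele", call. = FALSE)
  }
  xs <- sort(unique(m$x))
  ys <- sort(unique(m$y))
  nc <- length(xs)
  nr <- length(ys)
  if (nc < 2L || nr < 2L || nrow(m) != nc * nr) {
    stop("LUT format error: measurements do not form a rectangular grid",
         call. = FALSE)
  }
  expect_x <- rep(xs, times = nr)
  expect_y <- rep(ys, each = nc)
  if (any(m$x != expect_x) || any(m$y != expect_y)) {
    stop("LUT format error: rows are not in row-major grid order",
         call. = FALSE)
  }
  azi <- matrix(m$azi, nrow = nc, ncol = nr)  # [x index, y index]
  ele <- matrix(m$ele, nrow = nc, ncol = nr)
  if (!all(apply(azi, 2, function(v) all(diff(v) > 0) || all(diff(v) < 0)))) {
    stop("LUT format error: azimuth not monotone along the x axis",
         call. = FALSE)
  }
  if (!all(apply(ele, 1, function(v) all(diff(v) > 0) || all(diff(v) < 0)))) {
    stop("LUT format error: elevation not monotone along the y axis",
         call. = FALSE)
  }
  structure(
    list(x = xs, y = ys, azi = azi, ele = ele,
         n_cols = nc, n_rows = nr),
    class = "projection_lut"
  )
}

#' @export
print.projection_lut <- function(x, ...) {
  cat(sprintf("Projection LUT: %d x %d raster (%d nodes), azi [%.1f, %.1f], ele [%.1f, %.1f]\n",
              x$n_cols, x$n_rows, x$n_cols * x$n_rows,
              min(x$azi), max(x$azi), min(x$ele), max(x$ele)))
  invisible(x)
}

# invert the bilinear map of one grid cell: given corner angles (a00..a11,
# e00..e11) find (u, v) in [0,1]^2 with A(u,v)=azi, E(u,v)=ele, by Newton
# iteration from the cell center; returns c(u, v) or NULL if no solution in
# the cell
invert_cell_bilinear <- function(a, e, azi, ele, tol = 1e-12, maxit = 50L) {
  u <- 0.5
  v <- 0.5
  for (it in seq_len(maxit)) {
    A <- (1 - u) * (1 - v) * a[1] + u * (1 - v) * a[2] +
      (1 - u) * v * a[3] + u * v * a[4]
    E <- (1 - u) * (1 - v) * e[1] + u * (1 - v) * e[2] +
      (1 - u) * v * e[3] + u * v * e[4]
    f1 <- A - azi
    f2 <- E - ele
    if (abs(f1) < tol && abs(f2) < tol) break
    dAu <- (1 - v) * (a[2] - a[1]) + v * (a[4] - a[3])
    dAv <- (1 - u) * (a[3] - a[1]) + u * (a[4] - a[2])
    dEu <- (1 - v) * (e[2] - e[1]) + v * (e[4] - e[3])
    dEv <- (1 - u) * (e[3] - e[1]) + u * (e[4] - e[2])
    det <- dAu * dEv - dAv * dEu
    if (!is.finite(det) || abs(det) < 1e-300) return(NULL)
    u <- u - (f1 * dEv - f2 * dAv) / det
    v <- v - (f2 * dAu - f1 * dEu) / det
    # keep Newton from wandering far outside the cell
    u <- min(2, max(-1, u))
    v <- min(2, max(-1, v))
  }
  slack <- 1e-8
  if (u < -slack || u > 1 + slack || v < -slack || v > 1 + slack) return(NULL)
  c(min(1, max(0, u)), min(1, max(0, v)))
}

#' Map dome angles to projector pixels
#'
#' Looks up the grid cell whose measured angle quadrilateral contains the
#' query, inverts the cell's bilinear angle map, and interpolates the pixel
#' coordinates at the recovered cell-local position. Queries at LUT nodes
#' return the node pixels exactly, and the interpolation is exact whenever
#' the pixel-to-angle calibration is affine.
#'
#' @param lut A [build_lut()] object.
#' @param azi,ele Query azimuth(s) and elevation(s) in degrees (recycled to a
#'   common length).
#' @return Data frame with columns `x`, `y` (projector pixels).
#' @export
project <- function(lut, azi, ele) {
  stopifnot(inherits(lut, "projection_lut"))
  n <- max(length(azi), length(ele))
  azi <- rep_len(azi, n)
  ele <- rep_len(ele, n)
  out_x <- numeric(n)
  out_y <- numeric(n)
  nc <- lut$n_cols
  nr <- lut$n_rows
  for (q in seq_len(n)) {
    found <- FALSE
    for (j in seq_len(nr - 1L)) {
      for (i in seq_len(nc - 1L)) {
        a <- c(lut$azi[i, j], lut$azi[i + 1L, j],
               lut$azi[i, j + 1L], lut$azi[i + 1L, j + 1L])
        e <- c(lut$ele[i, j], lut$ele[i + 1L, j],
               lut$ele[i, j + 1L], lut$ele[i + 1L, j + 1L])
        pad <- 1e-9 + 1e-9 * max(abs(a), abs(e))
        if (azi[q] < min(a) - pad || azi[q] > max(a) + pad ||
            ele[q] < min(e) - pad || ele[q] > max(e) + pad) next
        uv <- invert_cell_bilinear(a, e, azi[q], ele[q])
        if (is.null(uv)) next
        u <- uv[1]
        v <- uv[2]
        out_x[q] <- (1 - u) * lut$x[i] + u * lut$x[i + 1L]
        out_y[q] <- (1 - v) * lut$y[j] + v * lut$y[j + 1L]
        found <- TRUE
        break
      }
      if (found) break
    }
    if (!found) {
      stop(sprintf("query (azi=%.3f, ele=%.3f) is outside the LUT grid",
                   azi[q], ele[q]), call. = FALSE)
    }
  }
  data.frame(x = out_x, y = out_y)
}

#' Read / write a LUT calibration file
#'
#' Plain CSV with header `x,y,azi,ele`, row-major in grid order.
#'
#' @param path CSV path.
#' @return `read_lut_csv()` returns a `projection_lut`; `write_lut_csv()`
#'   returns `path` invisibly.
#' @export
read_lut_csv <- function(path) {
  build_lut(utils::read.csv(path))
}

#' @rdname read_lut_csv
#' @param lut A `projection_lut`.
#' @export
write_lut_csv <- function(lut, path) {
  stopifnot(inherits(lut, "projection_lut"))
  df <- data.frame(
    x = rep(lut$x, times = lut$n_rows),
    y = rep(lut$y, each = lut$n_cols),
    azi = as.vector(lut$azi),
    ele = as.vector(lut$ele)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
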