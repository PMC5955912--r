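# degree-based trigonometry; the public interface works in degrees throughout
sind <- function(x) sin(x * pi / 180)
cosd <- function(x) cos(x * pi / 180)
asind <- function(x) asin(pmin(1, pmax(-1, x))) * 180 / pi

# run `expr` under a temporary RNG state seeded with `seed`; NULL leaves the
# global stream untouched so callers can manage seeding themselves
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# population (divide-by-n) moments, used by the across-mouse normalization so
# that its algebraic identities hold exactly
pvar <- function(x) mean((x - mean(x))^2)
psd <- function(x) sqrt(pvar(x))
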