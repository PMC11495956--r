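#' Daily nectar-sugar phenology curve
#'
#' A `phenology_curve` holds the estimated daily nectar sugar production of
#' one habitat, in grams of sucrose-equivalent sugar per square metre per
#' 24 h, on a 1-based day-of-year grid, together with a pointwise standard
#' error band.
#'
#' @param habitat habitat label.
#' @param day integer day-of-year grid (strictly increasing, within 1..365).
#' @param value grams sugar per m2 per day at each grid day; must be
#'   non-negative.
#' @param se pointwise standard error (same length as `value`); non-negative.
#' @param n_obs number of observations supporting the estimate.
#'
#' @return An object of class `phenology_curve`: a list with elements
#'   `habitat`, `day`, `value`, `se`, `n_obs`.
#' @export
phenology_curve <- function(habitat, day, value, se = rep(0, length(value)),
                            n_obs = NA_integer_) {
  day <- as.integer(day)
  if (length(day) < 2L || any(diff(day) <= 0L))
    stop("`day` must be a strictly increasing grid", call. = FALSE)
  if (any(day < 1L) || any(day > DAYS_PER_YEAR))
    stop("`day` must lie within 1..365", call. = FALSE)
  if (length(value) != length(day) || length(se) != length(day))
    stop("`value` and `se` must match the grid length", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("curve values must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(se)) || any(se < 0))
    stop("`se` must be finite and non-negative", call. = FALSE)
  structure(list(habitat = as.character(habitat), day = day,
                 value = as.numeric(value), se = as.numeric(se),
                 n_obs = as.integer(n_obs)),
            class = "phenology_curve")
}

#' @export
print.phenology_curve <- function(x, ...) {
  cat(sprintf("phenology curve: %s\n", x$habitat))
  cat(sprintf("  grid: days %d-%d (%d days)\n", min(x$day), max(x$day),
              length(x$day)))
  cat(sprintf("  peak: %.4g g m-2 day-1 on day %d\n", max(x$value),
              x$day[which.max(x$value)]))
  cat(sprintf("  annual integral: %.4g g m-2\n", curve_integral(x)))
  invisible(x)
}

#' @export
plot.phenology_curve <- function(x, ...) {
  graphics::plot(x$day, x$value, type = "l", xlab = "day of year",
                 ylab = expression(g ~ sugar ~ m^-2 ~ day^-1),
                 main = x$habitat, ...)
  if (any(x$se > 0)) {
    graphics::lines(x$day, pmax(0, x$value - x$se), lty = 3)
    graphics::lines(x$day, x$value + x$se, lty = 3)
  }
  invisible(x)
}

#' Annual integral of a phenology curve
#'
#' Trapezoidal quadrature of the curve over its day grid, in grams sugar per
#' m2 per year (for a full-season grid).
#'
#' @param curve a [phenology_curve()].
#' @return numeric scalar.
#' @export
curve_integral <- function(curve) {
  stopifnot(inherits(curve, "phenology_curve"))
  trapz(curve$day, curve$value)
}

#' Evaluate a curve at arbitrary days
#'
#' Linear interpolation within the grid; zero outside it.
#'
#' @param curve a [phenology_curve()].
#' @param days days of year.
#' @return numeric vector of values.
#' @export
curve_value <- function(curve, days) {
  stopifnot(inherits(curve, "phenology_curve"))
  stats::approx(curve$day, curve$value, xout = days, rule = 1)$y -> v
  v[is.na(v)] <- 0
  v
}

#' Locate prominent local maxima of a curve
#'
#' Finds interior strict local maxima and filters them by prominence: a
#' maximum is kept when it stands at least `min_prominence` (as a fraction of
#' the curve maximum) above the deepest valley separating it from a higher
#' maximum. Used to check that smoothing preserves the bimodal farmland
#' phenology.
#'
#' @param curve a [phenology_curve()] or numeric vector.
#' @param min_prominence minimum prominence as a fraction of the global
#'   maximum (default 0.1).
#' @return integer vector of grid indices (or days when a curve is given) of
#'   the retained maxima.
#' @export
curve_maxima <- function(curve, min_prominence = 0.1) {
  v <- if (inherits(curve, "phenology_curve")) curve$value else as.numeric(curve)
  n <- length(v)
  if (n < 3L || max(v) <= 0) return(integer(0))
  # plateau-tolerant local maxima
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (v[1L] > v[2L]) cand <- c(1L, cand)
  if (v[n] > v[n - 1L]) cand <- c(cand, n)
  if (length(cand) == 0L) return(integer(0))
  thr <- min_prominence * max(v)
  keep <- vapply(cand, function(k) {
    higher <- cand[v[cand] > v[k]]
    if (length(higher) == 0L) return(TRUE)  # global maximum
    # deepest valley between k and the nearest higher peak on each side
    prom <- Inf
    for (h in higher) {
      rng <- if (h < k) h:k else k:h
      prom <- min(prom, v[k] - min(v[rng]))
    }
    prom >= thr
  }, logical(1))
  out <- cand[keep]
  if (inherits(curve, "phenology_curve")) curve$day[out] else out
}

#' Rescale a curve to unit maximum
#'
#' Divides values (and standard errors) by the curve maximum so habitats of
#' very different productivity can be compared on phenological shape alone.
#'
#' @param curve a [phenology_curve()] with a positive maximum.
#' @return a [phenology_curve()] with `max(value) == 1`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "phenology_curve"))
  m <- max(curve$value)
  if (m <= 0)
    stop("cannot normalize an all-zero curve", call. = FALSE)
  phenology_curve(curve$habitat, curve$day, curve$value / m, curve$se / m,
                  curve$n_obs)
}

#' Write/read a curve as CSV (columns day, value, se)
#'
#' @param curve a [phenology_curve()].
#' @param path file path.
#' @return `read_curve_csv` returns a [phenology_curve()];
#'   `write_curve_csv` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "phenology_curve"))
  utils::write.csv(data.frame(day = curve$day, value = curve$value,
                              se = curve$se), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param habitat habitat label to attach on read.
#' @export
read_curve_csv <- function(path, habitat = NA_character_) {
  d <- utils::read.csv(path)
  phenology_curve(habitat, d$day, d$value, d$se %||% rep(0, nrow(d)))
}
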