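# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed from a master seed and index terms; stays < 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(h)
}

# Trapezoidal quadrature on an arbitrary grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

DAYS_PER_YEAR <- 365L
.month_ends <- cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L))

# Month (1-12) of a 1-based day of year; no leap handling.
month_of_doy <- function(day) {
  findInterval(day - 1L, c(0L, .month_ends[-12L]))
}

# Day of year (1-based) for Date input.
doy <- function(dates) as.POSIXlt(dates)$yday + 1L

# 15th day of each month as day-of-year.
mid_month_doy <- function() c(0L, .month_ends[-12L]) + 15L

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}
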