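#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used by most clinical registries (and by SPSS), rather than base R's
#' round-half-even. Used for every percentage the package reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(87.25, 1) # 87.3, not 87.2
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # 1e-9 guards against values like 96.95 stored as 96.94999...
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derived from a root seed. Keeps results of one
# pipeline stage invariant when an upstream stage's internal draw count changes.
#' @noRd
derive_seed <- function(root_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 7919 + h * 131) %% 2147483647L)
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Integer waiting times (days) with a configurable median: target + a symmetric
# difference of two negative-binomial draws, truncated at `min`. The symmetric
# construction keeps the median at `target` while giving realistic over-
# dispersed day counts.
#' @noRd
rwait_days <- function(n, median, spread_mu = 2, spread_size = 3, min = 1) {
  d <- stats::rnbinom(n, size = spread_size, mu = spread_mu) -
    stats::rnbinom(n, size = spread_size, mu = spread_mu)
  pmax(min, median + d)
}

# All weekday (Mon-Fri) dates of a calendar year.
#' @noRd
year_weekdays <- function(year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  days[as.POSIXlt(days)$wday %in% 1:5]
}

# First date with the given weekday (0 = Sunday ... 6 = Saturday) strictly
# after `date`. Vectorised over `date`.
#' @noRd
next_weekday <- function(date, wday) {
  off <- (wday - as.POSIXlt(date + 1)$wday) %% 7
  date + 1 + off
}
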