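#' Periodic monotone cubic Hermite (PCHIP) interpolation
#'
#' Builds a C1, period-`period` piecewise-cubic Hermite interpolant
#' through the knots, with Fritsch-Carlson derivative limiting applied
#' with wrap-around at the seam so that every knot -- including the first
#' and last -- is treated as interior. The interpolant preserves
#' monotonicity on monotone knot runs, reproduces constants exactly, and
#' matches value and first derivative at `t = 0` and `t = period`.
#'
#' @param knot_times strictly increasing times in `[0, period)`; at least
#'   3 knots.
#' @param knot_values values at the knots.
#' @param period the period (default 24 hours).
#' @return A vectorised function of time `t` (class `periodic_pchip`)
#'   with attributes `knots`, `values`, `derivs`, `period`.
#' @export
periodic_pchip <- function(knot_times, knot_values, period = 24) {
  x <- as.numeric(knot_times)
  y <- as.numeric(knot_values)
  n <- length(x)
  if (length(y) != n) stop("knot_times and knot_values differ in length")
  if (n < 3) stop("periodic PCHIP needs at least 3 knots")
  if (anyDuplicated(x) || any(diff(x) <= 0)) {
    stop("knot times must be strictly increasing and distinct")
  }
  if (any(x < 0) || any(x >= period)) {
    stop("knot times must lie in [0, period)")
  }
  # interval widths and secant slopes, wrapping the last interval
  h <- c(diff(x), x[1] + period - x[n])
  delta <- c(diff(y), y[1] - y[n]) / h
  # Fritsch-Carlson limited derivative at every knot (all interior on the
  # circle); previous interval of knot k is k-1, wrapping to n for k = 1
  prev <- c(n, seq_len(n - 1))
  d <- numeric(n)
  for (k in seq_len(n)) {
    d1 <- delta[prev[k]]
    d2 <- delta[k]
    if (d1 * d2 > 0) {
      w1 <- 2 * h[k] + h[prev[k]]
      w2 <- h[k] + 2 * h[prev[k]]
      d[k] <- (w1 + w2) / (w1 / d1 + w2 / d2)
    } # else leaves d[k] = 0 (local extremum or flat)
  }
  xe <- c(x, x[1] + period)
  ye <- c(y, y[1])
  de <- c(d, d[1])
  f <- function(t) {
    tm <- as.numeric(t) %% period
    tm[tm < x[1]] <- tm[tm < x[1]] + period
    i <- findInterval(tm, xe, rightmost.closed = TRUE)
    i[i > n] <- n
    hi <- xe[i + 1] - xe[i]
    s <- (tm - xe[i]) / hi
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    h00 * ye[i] + h10 * hi * de[i] + h01 * ye[i + 1] + h11 * hi * de[i + 1]
  }
  structure(f, knots = x, values = y, derivs = d, period = period,
            class = c("periodic_pchip", "function"))
}
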