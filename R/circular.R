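#' Signed circular timing error
#'
#' The circular difference `T - T_a` mapped into `(-12, 12]` hours, with
#' `+12` preferred at the antipodal boundary. This is the apparent timing
#' error of an estimated phase `T` against the sample collection time
#' `T_a`.
#'
#' @param T estimated time(s) in hours.
#' @param T_a reference time(s) in hours.
#' @return numeric vector of signed errors in `(-12, 12]`.
#' @export
signed_circular_error <- function(T, T_a) {
  e <- (T - T_a) %% 24
  ifelse(e > 12, e - 24, e)
}

#' Circular mean of times of day
#'
#' Mean direction of the angles `2*pi*t/24`, returned in hours. When the
#' mean resultant length is below `min_resultant` the mean direction is
#' poorly determined and `NA` is returned (with a warning).
#'
#' @param t times in hours.
#' @param min_resultant threshold on the mean resultant length below which
#'   the mean is declared undefined (default 0.1).
#' @return circular mean in `[0, 24)`, or `NA`.
#' @export
circular_mean_hours <- function(t, min_resultant = 0) {
  a <- 2 * pi * t / 24
  s <- mean(sin(a))
  c <- mean(cos(a))
  r <- sqrt(s^2 + c^2)
  if (r < min_resultant) {
    warning("circular mean undefined: resultant length ",
            format(r, digits = 3), " below ", min_resultant)
    return(NA_real_)
  }
  m <- (atan2(s, c) * 24 / (2 * pi)) %% 24
  if (24 - m < 1e-9) m <- 0  # guard the 24 == 0 seam against rounding
  m
}

# circular mean of *signed* differences in (-12, 12]: map the hours onto
# the circle, take the mean direction, map back preferring +12 at the
# boundary.
circular_mean_signed <- function(e, min_resultant = 0.1) {
  m <- circular_mean_hours(e %% 24, min_resultant = min_resultant)
  if (is.na(m)) return(NA_real_)
  if (m > 12) m - 24 else m
}

# Root-mean-square circular deviation (hours) of times from their
# circular mean; 0 for perfectly synchronised phases. For two angles one
# hour either side of the mean this is exactly 1 h.
circular_dispersion_hours <- function(t) {
  m <- circular_mean_hours(t)
  if (is.na(m)) return(NA_real_)
  sqrt(mean(signed_circular_error(t, m)^2))
}
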