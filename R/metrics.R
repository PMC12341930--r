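#' Maximum specific growth rate from an OD time series
#'
#' The classical log-linear sliding-window estimator: over every window of
#' `window_points` consecutive samples whose ODs all exceed `od_floor`, the
#' slope of `ln(od)` versus time is computed by least squares; the largest
#' slope (floored at 0) is the maximum specific growth rate.  The default
#' window of 5 samples spans 2.5 h at the half-hour plate-reader cadence;
#' the OD floor of 0.02 suppresses read-noise at the detection limit.
#'
#' @param t Time (hours, strictly increasing).
#' @param od OD600 series, same length as `t`.
#' @param window_points Samples per sliding window (>= 3).
#' @param od_floor Minimum OD for a sample to enter a window.
#' @return List with `mu_max` (per hour), `window` (`c(t_start, t_end)` of
#'   the best window), and `slope` (the unfloored best slope).
#' @examples
#' t <- seq(0, 10, 0.5)
#' max_specific_growth_rate(t, 0.05 * exp(0.3 * t))$mu_max   # 0.3
#' @export
max_specific_growth_rate <- function(t, od, window_points = 5L,
                                     od_floor = 0.02) {
  stopifnot(is.numeric(t), is.numeric(od), length(t) == length(od),
            window_points >= 3L)
  if (any(diff(t) <= 0)) {
    stop("max_specific_growth_rate: t must be strictly increasing",
         call. = FALSE)
  }
  ok <- od > od_floor
  n <- length(t)
  best <- -Inf; best_win <- c(NA_real_, NA_real_)
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    if (!all(ok[idx])) next
    tw <- t[idx]; lw <- log(od[idx])
    sl <- stats::cov(tw, lw) / stats::var(tw)
    if (sl > best) {
      best <- sl
      best_win <- c(tw[1L], tw[length(tw)])
    }
  }
  if (!is.finite(best)) {
    stop("max_specific_growth_rate: fewer than ", window_points,
         " consecutive samples above the OD floor of ", od_floor,
         call. = FALSE)
  }
  list(mu_max = max(best, 0), window = best_win, slope = best)
}

#' Lag time by the tangent method
#'
#' The tangent to `ln(od)` at the maximum-growth window is extrapolated
#' back to the initial OD level; the intersection time is the lag.  For a
#' pure exponential from t = 0 the lag is 0 (up to grid resolution); a
#' series that never grows raises a degenerate-data error.
#'
#' @inheritParams max_specific_growth_rate
#' @return Lag time in hours (floored at 0).
#' @export
lag_time <- function(t, od, window_points = 5L, od_floor = 0.02) {
  mu <- max_specific_growth_rate(t, od, window_points, od_floor)
  if (mu$slope <= 0) {
    stop("lag_time: no growth detected (mu_max <= 0)", call. = FALSE)
  }
  # tangent in log space through the window midpoint
  idx <- which(t >= mu$window[1L] & t <= mu$window[2L])
  t_mid <- mean(t[idx])
  l_mid <- mean(log(od[idx]))
  l0 <- log(od[1L])
  max(t_mid - (l_mid - l0) / mu$slope, 0)
}

#' Disaccharide conversion rate from HPLC depletion
#'
#' The magnitude of the least-squares slope of concentration versus time
#' over the depletion segment, i.e. the initial run of samples whose
#' concentration stays above `depletion_floor_fraction` of the starting
#' concentration.  The segment stops at the floor because concentrations
#' near the HPLC detection limit — and late-time evaporation, which
#' concentrates the remaining sugars — would otherwise bias the slope.
#' A series whose fitted slope is non-negative (no depletion) returns 0
#' with attribute `no_depletion = TRUE`.
#'
#' @param t Time (hours, strictly increasing).
#' @param conc Disaccharide concentration (g/l), same length as `t`.
#' @param depletion_floor_fraction Segment ends when concentration first
#'   drops below this fraction of the initial value (default 0.1).
#' @return Conversion rate in g/l/h (non-negative scalar) with attributes
#'   `segment` (`c(t_start, t_end)`), `n_points`, and `no_depletion`.
#' @examples
#' t <- seq(0, 48, length.out = 16)
#' conversion_rate(t, pmax(2 - 0.014 * t, 0))   # 0.014
#' @export
conversion_rate <- function(t, conc, depletion_floor_fraction = 0.1) {
  stopifnot(is.numeric(t), is.numeric(conc), length(t) == length(conc))
  if (any(diff(t) <= 0)) {
    stop("conversion_rate: t must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) {
    stop("conversion_rate: concentrations must be non-negative",
         call. = FALSE)
  }
  floor_conc <- depletion_floor_fraction * conc[1L]
  below <- which(conc < floor_conc)
  last <- if (length(below)) below[1L] - 1L else length(t)
  if (last < 4L) {
    stop("conversion_rate: need at least 4 points in the depletion segment ",
         "(got ", max(last, 0L), ")", call. = FALSE)
  }
  idx <- seq_len(last)
  sl <- stats::cov(t[idx], conc[idx]) / stats::var(t[idx])
  no_dep <- sl >= 0
  if (no_dep) {
    warning("conversion_rate: series is not depleting (slope = ",
            format(sl, digits = 3), "); returning 0", call. = FALSE)
  }
  out <- if (no_dep) 0 else abs(sl)
  attr(out, "segment") <- c(t[1L], t[last])
  attr(out, "n_points") <- last
  attr(out, "no_depletion") <- no_dep
  out
}

#' Growth summary of an OD time series
#'
#' Convenience wrapper bundling the maximum specific growth rate, its
#' window, the tangent lag time, and the final OD.
#'
#' @inheritParams max_specific_growth_rate
#' @return List with `mu_max`, `mu_max_window`, `lag_h`, `final_od`.
#' @export
growth_summary <- function(t, od, window_points = 5L, od_floor = 0.02) {
  mu <- max_specific_growth_rate(t, od, window_points, od_floor)
  lag <- if (mu$slope > 0) {
    lag_time(t, od, window_points, od_floor)
  } else {
    NA_real_
  }
  list(mu_max = mu$mu_max, mu_max_window = mu$window, lag_h = lag,
       final_od = od[length(od)])
}
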