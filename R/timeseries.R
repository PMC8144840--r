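#' Detrend a single-cell intensity time series
#'
#' Removes the slow trend (cell state / technical drift, timescale several
#' times the ultradian period) from a single-cell trace and z-scores the
#' result, leaving the oscillatory component on a comparable scale across
#' cells. The trend is a local polynomial (loess) fit whose span is chosen
#' so that only variation slower than `trend_window_h` survives in the
#' trend; a global polynomial alternative is available.
#'
#' @param x intensity series (>= 20 points on a regular grid).
#' @param times_min sample times, min (default unit spacing).
#' @param method `"loess"` (default) or `"poly"`.
#' @param trend_window_h trend timescale, hours; should be >= 3x the
#'   expected oscillation period (default 10 h for a ~3.3 h period).
#' @param poly_order order of the global polynomial for `method = "poly"`.
#' @param zscore z-score the detrended series (default TRUE).
#' @return List with `detrended`, `trend`, `times_min`.
#' @export
detrend_timeseries <- function(x, times_min = seq_along(x) - 1,
                               method = c("loess", "poly"),
                               trend_window_h = 10, poly_order = 3,
                               zscore = TRUE) {
  method <- match.arg(method)
  if (length(x) < 20L) stop("series too short to detrend (need >= 20 points)", call. = FALSE)
  if (length(times_min) != length(x)) stop("times and series lengths differ", call. = FALSE)
  if (method == "loess") {
    span <- min(1, (trend_window_h * 60) / diff(range(times_min)))
    span <- max(span, 10 / length(x))  # keep enough points in the window
    fit <- stats::loess(x ~ times_min, span = span, degree = 2,
                        family = "gaussian")
    trend <- stats::fitted(fit)
  } else {
    fit <- stats::lm(x ~ stats::poly(times_min, poly_order))
    trend <- stats::fitted(fit)
  }
  d <- x - trend
  if (zscore) {
    s <- stats::sd(d)
    if (s > 0) d <- (d - mean(d)) / s
  }
  list(detrended = d, trend = trend, times_min = times_min)
}

#' Ultradian period of single-cell traces
#'
#' Measures the mean temporal period of each cell's protein trace after
#' detrending, either from the unwrapped Hilbert phase (total phase
#' progression divided into 2*pi cycles) or from the mean spacing of
#' upward zero crossings of the detrended signal.
#'
#' @param sim a `"hes_sim"` from [simulate_hes5()], or a numeric matrix of
#'   traces (cells x timepoints).
#' @param times_min sample times when `sim` is a matrix.
#' @param method `"hilbert"` (default) or `"zero_crossing"`.
#' @param trend_window_h passed to [detrend_timeseries()].
#' @return List with `period_h` per cell and `mean_period_h`.
#' @export
temporal_period <- function(sim, times_min = NULL,
                            method = c("hilbert", "zero_crossing"),
                            trend_window_h = 10) {
  method <- match.arg(method)
  if (inherits(sim, "hes_sim")) {
    mat <- sim$protein
    times_min <- sim$times
  } else {
    mat <- as.matrix(sim)
    if (is.null(times_min)) times_min <- seq_len(ncol(mat)) - 1
  }
  dur_min <- diff(range(times_min))
  per <- apply(mat, 1L, function(x) {
    d <- detrend_timeseries(x, times_min, trend_window_h = trend_window_h)$detrended
    if (stats::sd(d) == 0) return(NA_real_)
    if (method == "hilbert") {
      ph <- analytic_phase(d)$phase
      up <- unwrap_phase(ph)
      cycles <- (up[length(up)] - up[1]) / (2 * pi)
      if (cycles <= 0.5) return(NA_real_)
      dur_min / cycles / 60
    } else {
      s <- sign(d)
      ups <- which(diff(s >= 0) == 1)
      if (length(ups) < 2L) return(NA_real_)
      mean(diff(times_min[ups])) / 60
    }
  })
  list(period_h = per, mean_period_h = mean(per, na.rm = TRUE))
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}
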