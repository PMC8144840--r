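#' Instantaneous phase and amplitude via the analytic signal
#'
#' Reconstructs the instantaneous phase of a detrended oscillatory signal
#' from its analytic signal `u + i H[u]`, where `H` is the Hilbert
#' transform computed by the discrete (FFT) route. The ends are tapered
#' with a 10% Tukey window before transforming to suppress edge artefacts;
#' the untapered signal is used for the real part.
#'
#' @param x numeric vector, a detrended (approximately zero-mean) signal
#'   sampled on a regular grid; length >= 8.
#' @param taper total fraction of the record cosine-tapered (default 0.1);
#'   0 disables tapering.
#' @return A list of class `"phase_series"` with `phase` (radians in
#'   `[0, 2*pi)`) and `amplitude`.
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.1)
#' ph <- analytic_phase(sin(2 * pi * t / 5))
#' range(ph$phase)
analytic_phase <- function(x, taper = 0.1) {
  if (length(x) < 8L) stop("signal too short for phase reconstruction (need >= 8)", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps^0.5 * (abs(mean(x)) + 1)) {
    stop("degenerate (constant) signal: phase undefined", call. = FALSE)
  }
  xt <- x * tukey_window(length(x), taper)
  h <- analytic_signal(xt)
  structure(list(phase = Arg(h) %% (2 * pi), amplitude = Mod(h)),
            class = "phase_series")
}

# discrete analytic signal: zero the negative frequencies, double positives
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2 + 1L] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1L] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

tukey_window <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

#' Kuramoto order parameter
#'
#' `KOP(t) = | (1/N) sum_j exp(i phi_j(t)) |`, the resultant length of the
#' oscillator phases at each timepoint: 1 means perfect phase synchrony,
#' values near `1/sqrt(N)` are the incoherent noise floor.
#'
#' @param phases numeric matrix of phases in radians, oscillators x
#'   timepoints (a vector is treated as one timepoint).
#' @return A list of class `"kop_result"`: `kop_per_time`, `mean_kop`,
#'   `n_oscillators`.
#' @export
#' @examples
#' kuramoto_order(matrix(c(0, 0, pi / 2, pi / 2), 2))$kop_per_time
kuramoto_order <- function(phases) {
  if (is.vector(phases)) phases <- matrix(phases, ncol = 1L)
  if (nrow(phases) < 2L) stop("need at least 2 oscillators", call. = FALSE)
  z <- colMeans(exp(1i * phases))
  kop <- Mod(z)
  structure(list(kop_per_time = kop, mean_kop = mean(kop),
                 n_oscillators = nrow(phases)), class = "kop_result")
}

#' @export
print.kop_result <- function(x, ...) {
  cat(sprintf("Kuramoto order parameter: mean %.3f over %d timepoints, N = %d oscillators\n",
              x$mean_kop, length(x$kop_per_time), x$n_oscillators))
  invisible(x)
}

#' Phase-phase density map for an oscillator pair
#'
#' Bins the joint instantaneous phases of two co-recorded oscillators on a
#' `bins x bins` grid over `[0, 2*pi)^2` and summarises phase locking as
#' the likelihood ratio of in-phase occupancy (wrapped phase difference
#' within `band` of 0) to out-of-phase occupancy (within `band` of pi).
#'
#' @param phase_a,phase_b phases in radians (equal length, >= 10 points),
#'   or `"phase_series"` objects.
#' @param bins grid resolution per axis (default 24).
#' @param band half-width of the in/out-of-phase bands, radians
#'   (default `pi/4`).
#' @return List with `density` (bins x bins counts, a-phase rows),
#'   `likelihood_in_out`, `frac_in`, `frac_out`.
#' @export
phase_phase_density <- function(phase_a, phase_b, bins = 24L, band = pi / 4) {
  pa <- if (inherits(phase_a, "phase_series")) phase_a$phase else phase_a
  pb <- if (inherits(phase_b, "phase_series")) phase_b$phase else phase_b
  keep <- is.finite(pa) & is.finite(pb)
  pa <- pa[keep] %% (2 * pi); pb <- pb[keep] %% (2 * pi)
  if (length(pa) != length(pb)) stop("phase series must be co-recorded", call. = FALSE)
  if (length(pa) < 10L) stop("insufficient co-existing timepoints (need >= 10)", call. = FALSE)
  cut_a <- pmin(floor(pa / (2 * pi) * bins) + 1L, bins)
  cut_b <- pmin(floor(pb / (2 * pi) * bins) + 1L, bins)
  dens <- matrix(0L, bins, bins)
  for (i in seq_along(cut_a)) dens[cut_a[i], cut_b[i]] <- dens[cut_a[i], cut_b[i]] + 1L
  dphi <- wrap_pi(pa - pb)
  n_in <- sum(abs(dphi) < band)
  n_out <- sum(abs(abs(dphi) - pi) < band)
  list(density = dens,
       likelihood_in_out = (n_in + 0.5) / (n_out + 0.5),
       frac_in = n_in / length(dphi), frac_out = n_out / length(dphi))
}

# wrap angles to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Phase shift between two series by cross-correlation
#'
#' The phase shift is the lag closest to zero at which the
#' cross-correlation function of the two detrended series has a local
#' maximum. Used both for cell-pair time series (lag in time) and for
#' spatial profiles (lag in micrometres).
#'
#' @param a,b equal-length detrended numeric series.
#' @param dx axis step per sample (min or um); lags are reported in these
#'   units. Default 1 (lag in samples).
#' @param max_lag maximum lag scanned, in samples (default half the
#'   record).
#' @return List with `lag` (signed, units of `dx`; positive when `a` leads
#'   `b`, i.e. `b` reproduces `a` with that delay), `lags`, `ccf` (the
#'   full cross-correlation function).
#' @export
xcorr_phase_shift <- function(a, b, dx = 1, max_lag = NULL) {
  if (length(a) != length(b)) stop("series must have equal length", call. = FALSE)
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("flat signal: cross-correlation undefined", call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- floor(n / 2)
  cc <- stats::ccf(a, b, lag.max = max_lag, plot = FALSE, demean = TRUE)
  lags <- -as.vector(cc$lag)  # sign so that a positive lag means a leads b
  r <- as.vector(cc$acf)
  # local maxima (interior); plateau-tolerant
  pk <- which(diff(sign(diff(r))) < 0) + 1L
  if (length(pk) == 0L) {
    # monotone or flat ccf: fall back to the global maximum if informative
    if (max(r) - min(r) < 1e-12) stop("flat cross-correlation: no peak", call. = FALSE)
    pk <- which.max(r)
  }
  best <- pk[which.min(abs(lags[pk]))]
  list(lag = lags[best] * dx, lags = lags * dx, ccf = r)
}

#' Phase synchronisation index of a kymograph phase map
#'
#' Quantifies how frozen-in-place a spatially periodic pattern is: the
#' phases of one dorsoventral position across 2-h timeblocks are treated
#' as an oscillator set, their KOP is computed per position, and the
#' index is the average over positions. A pattern whose peaks and troughs
#' never move scores ~1; frequent phase resets (high/low switching at the
#' same location) drive the index towards the finite-sample noise floor.
#'
#' @param pm a phase map from [phase_map()], or a numeric positions x
#'   timeblocks phase matrix (radians; NA columns are excluded).
#' @param periodic_only if `TRUE` (default) and `pm` carries per-block
#'   periodicity flags, only blocks whose spatial profile passed the
#'   autocorrelation periodicity test are used.
#' @return List with `index` (scalar), `kop_per_position`,
#'   `n_blocks_used`.
#' @export
phase_sync_index <- function(pm, periodic_only = TRUE) {
  if (inherits(pm, "phase_map")) {
    keep <- pm$valid
    # blocks that failed the periodicity test are dropped; untested (NA)
    # blocks are kept
    if (periodic_only && !is.null(pm$periodic)) {
      keep <- keep & !(pm$periodic %in% FALSE)
    }
    mat <- pm$phase[, keep, drop = FALSE]
  } else {
    mat <- as.matrix(pm)
    mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
  }
  if (ncol(mat) < 3L) stop("fewer than 3 valid timeblocks: cannot score synchrony", call. = FALSE)
  kop_pos <- apply(mat, 1L, function(ph) Mod(mean(exp(1i * ph))))
  list(index = mean(kop_pos), kop_per_position = kop_pos,
       n_blocks_used = ncol(mat))
}

#' Kuramoto order parameter of a lattice simulation
#'
#' Convenience pipeline from simulation to synchrony score: each cell's
#' protein trace is detrended ([detrend_timeseries()]), its
#' instantaneous phase reconstructed ([analytic_phase()]), and the
#' Kuramoto order parameter computed per timepoint and averaged.
#'
#' @param sim a `"hes_sim"` from [simulate_hes5()].
#' @param trend_window_h detrending timescale, hours (default 10).
#' @return A `"kop_result"` (see [kuramoto_order()]).
#' @export
sim_kop <- function(sim, trend_window_h = 10) {
  stopifnot(inherits(sim, "hes_sim"))
  ph <- t(apply(sim$protein, 1, function(x) {
    analytic_phase(detrend_timeseries(x, sim$times,
                                      trend_window_h = trend_window_h)$detrended)$phase
  }))
  kuramoto_order(ph)
}
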