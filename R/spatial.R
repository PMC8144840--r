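#' Detrend a spatial expression profile
#'
#' Removes the slow dorsoventral trend (the bell-shaped expression domain)
#' from a raw spatial intensity profile by least-squares polynomial fit,
#' leaving the micro-pattern component whose periodicity is analysed
#' downstream.
#'
#' @param raw intensity values along the dorsoventral axis.
#' @param positions_um positions of the samples, micrometres
#'   (default regular unit grid).
#' @param poly_order trend polynomial order, 4-6 (default 4).
#' @return An object of class `"spatial_profile"`: list with
#'   `positions_um`, `raw`, `trend`, `detrended` (raw minus trend,
#'   mean ~ 0) and `poly_order`.
#' @export
detrend_spatial <- function(raw, positions_um = seq_along(raw) - 1,
                            poly_order = 4) {
  if (!(poly_order %in% 4:6)) stop("poly_order must be 4, 5 or 6", call. = FALSE)
  n <- length(raw)
  if (n < 3 * (poly_order + 1)) {
    stop("profile too short for an order-", poly_order, " trend fit", call. = FALSE)
  }
  if (length(positions_um) != n) stop("positions and profile lengths differ", call. = FALSE)
  if (stats::sd(raw) == 0) {
    trend <- raw
  } else {
    fit <- stats::lm(raw ~ stats::poly(positions_um, poly_order))
    if (any(!is.finite(stats::coef(fit)))) stop("ill-conditioned trend fit", call. = FALSE)
    trend <- as.vector(stats::fitted(fit))
  }
  structure(list(positions_um = positions_um, raw = raw, trend = trend,
                 detrended = raw - trend, poly_order = poly_order),
            class = "spatial_profile")
}

#' Spatial periodicity by bootstrap autocorrelation
#'
#' Computes the normalised autocorrelation function of a detrended spatial
#' profile, smooths it with a Savitzky-Golay filter, and identifies
#' significant peaks against a bootstrap null built by randomly shuffling
#' the position bins of the detrended profile (`n_boot` shuffles, each
#' re-autocorrelated). A peak is significant when the smoothed ACF exceeds
#' the null mean + 2 SD at that lag. The profile is called periodic when
#' at least two significant peaks exist; the spatial period is the mean
#' spacing of the significant peaks.
#'
#' @param profile a `"spatial_profile"` from [detrend_spatial()], or a
#'   detrended numeric vector.
#' @param um_per_bin spatial step, micrometres (inferred from the profile
#'   positions when available).
#' @param n_boot number of shuffles for the null (default 100).
#' @param seed RNG seed for the shuffles.
#' @param max_lag_frac largest lag scanned, as a fraction of the profile
#'   length (default 0.75).
#' @param sg_window,sg_order Savitzky-Golay smoothing window (bins, odd)
#'   and polynomial order.
#' @return An object of class `"autocorr_result"`: `lags_um`, `acf`
#'   (smoothed), `acf_raw`, `envelope` (null mean + 2 SD per lag),
#'   `significant_peak_lags_um`, `peak_to_peak_mean_um`, `is_periodic`.
#' @export
spatial_autocorr <- function(profile, um_per_bin = NULL, n_boot = 100,
                             seed = 1L, max_lag_frac = 0.75,
                             sg_window = 5, sg_order = 2) {
  x <- profile_values(profile)
  if (is.null(um_per_bin)) um_per_bin <- profile_step(profile)
  n <- length(x)
  if (n < 4) stop("profile shorter than 4 bins", call. = FALSE)
  lag_max <- max(3L, floor(n * max_lag_frac))
  a_raw <- acf_vec(x, lag_max)
  a_sm <- sg_smooth(a_raw, sg_window, sg_order)

  set.seed(seed)
  null_acf <- replicate(n_boot, {
    sg_smooth(acf_vec(sample(x), lag_max), sg_window, sg_order)
  })
  envelope <- rowMeans(null_acf) + 2 * apply(null_acf, 1, stats::sd)
  # peaks are max-selected, so the pointwise envelope alone under-controls
  # the false-alarm rate; also require peaks to clear the null ceiling
  # (mean + 2 SD of each shuffle's tallest smoothed-ACF peak)
  null_peak_max <- apply(null_acf, 2, function(a) {
    pk <- find_acf_peaks(a)
    if (length(pk)) max(a[pk]) else max(a)
  })
  peak_ceiling <- mean(null_peak_max) + 2 * stats::sd(null_peak_max)

  pk <- find_acf_peaks(a_sm)
  sig <- pk[a_sm[pk] > envelope[pk] & a_sm[pk] > peak_ceiling]
  lags_um <- (seq_len(lag_max)) * um_per_bin
  sig_um <- lags_um[sig]
  p2p <- if (length(sig) >= 2) mean(diff(sig_um)) else if (length(sig) == 1) sig_um else NA_real_
  structure(list(lags_um = lags_um, acf = a_sm, acf_raw = a_raw,
                 envelope = envelope,
                 significant_peak_lags_um = sig_um,
                 peak_to_peak_mean_um = p2p,
                 is_periodic = length(sig) >= 2,
                 peak_ceiling = peak_ceiling,
                 n_boot = n_boot),
            class = "autocorr_result")
}

profile_values <- function(profile) {
  if (inherits(profile, "spatial_profile")) profile$detrended else as.numeric(profile)
}
profile_step <- function(profile) {
  if (inherits(profile, "spatial_profile") && length(profile$positions_um) > 1) {
    diff(profile$positions_um[1:2])
  } else 1
}

# normalised autocorrelation at lags 1..lag_max (lag 0 == 1 dropped)
acf_vec <- function(x, lag_max) {
  as.vector(stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)[-1]
}

sg_smooth <- function(x, window, order) {
  if (length(x) <= window) return(x)
  as.vector(signal::sgolayfilt(x, p = order, n = window))
}

# interior local maxima of an ACF-like vector
find_acf_peaks <- function(a) {
  pk <- pracma::findpeaks(a)
  if (is.null(pk)) integer(0) else sort(pk[, 2])
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("Spatial autocorrelation: %d lags, %d significant peaks (%d-shuffle bootstrap)\n",
              length(x$lags_um), length(x$significant_peak_lags_um), x$n_boot))
  if (x$is_periodic) {
    cat(sprintf("  periodic: yes, mean peak-to-peak period %.1f um\n", x$peak_to_peak_mean_um))
  } else {
    cat("  periodic: no\n")
  }
  invisible(x)
}

#' Spatial period by Lomb-Scargle periodogram
#'
#' Classical normalised Lomb-Scargle periodogram of a detrended spatial
#' profile over periods from two bins to half the domain length.
#' Significance uses the standard false-alarm level
#' `1 - (1 - exp(-z))^M` with `M` the number of scanned frequencies;
#' periods whose false-alarm probability falls below `significance` are
#' reported. When two or more pass, the spatial period estimate is the
#' mean of the top two peaks by power.
#'
#' @inheritParams spatial_autocorr
#' @param significance false-alarm probability threshold (default 1e-4).
#' @param oversample frequency oversampling factor (default 4).
#' @return An object of class `"periodogram_result"`: `periods_um`,
#'   `power`, `power_threshold`, `significant_periods_um` (by descending
#'   power), `period_um` (top-2 mean, or the single significant period,
#'   or NA).
#' @export
lomb_scargle_period <- function(profile, um_per_bin = NULL,
                                significance = 1e-4, oversample = 4) {
  x <- profile_values(profile)
  if (is.null(um_per_bin)) um_per_bin <- profile_step(profile)
  n <- length(x)
  L <- n * um_per_bin
  t <- (seq_len(n) - 1) * um_per_bin
  # periods in [2 bins, L/2]
  f_min <- 2 / L
  f_max <- 1 / (2 * um_per_bin)
  n_f <- max(8L, ceiling((f_max - f_min) * L * oversample))
  freq <- seq(f_min, f_max, length.out = n_f)
  pw <- ls_power(t, x, freq)
  m_indep <- ceiling((f_max - f_min) * L)  # ~ independent frequencies
  thr <- -log(1 - (1 - significance)^(1 / m_indep))
  # significant local maxima of the power spectrum
  pk <- pracma::findpeaks(pw)
  pk_idx <- if (is.null(pk)) integer(0) else pk[, 2]
  if (length(pw) && which.max(pw) %in% c(1L, length(pw))) pk_idx <- c(pk_idx, which.max(pw))
  sig <- pk_idx[pw[pk_idx] > thr]
  sig <- sig[order(pw[sig], decreasing = TRUE)]
  sig_periods <- 1 / freq[sig]
  period <- if (length(sig) >= 2) mean(sig_periods[1:2]) else if (length(sig) == 1) sig_periods[1] else NA_real_
  structure(list(periods_um = 1 / freq, power = pw, power_threshold = thr,
                 significant_periods_um = sig_periods, period_um = period,
                 significance = significance),
            class = "periodogram_result")
}

# Scargle (1982) normalised periodogram
ls_power <- function(t, x, freq) {
  x <- x - mean(x)
  s2 <- stats::var(x)
  if (s2 == 0) return(rep(0, length(freq)))
  vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf("Lomb-Scargle periodogram: %d periods scanned, threshold power %.2f (FAP %g)\n",
              length(x$periods_um), x$power_threshold, x$significance))
  if (length(x$significant_periods_um)) {
    cat(sprintf("  significant periods (um): %s; estimate %.1f um\n",
                paste(sprintf("%.1f", x$significant_periods_um), collapse = ", "),
                x$period_um))
  } else cat("  no significant period\n")
  invisible(x)
}

#' Peak-to-trough fold changes of a spatial profile
#'
#' Raw-intensity fold changes between each significant peak of the
#' detrended profile and its adjacent trough (troughs found as peaks of
#' the negated signal).
#'
#' @param profile a `"spatial_profile"` (needs both `raw` and
#'   `detrended`).
#' @param acr optional precomputed [spatial_autocorr()] result used to
#'   gate on significant spatial structure; when supplied and not
#'   periodic, an empty result is returned.
#' @return List with `fold_changes`, `peak_positions_um`,
#'   `trough_positions_um`.
#' @export
peak_trough_fold_change <- function(profile, acr = NULL) {
  stopifnot(inherits(profile, "spatial_profile"))
  if (!is.null(acr) && !acr$is_periodic) {
    return(list(fold_changes = numeric(0), peak_positions_um = numeric(0),
                trough_positions_um = numeric(0)))
  }
  d <- profile$detrended
  pks <- find_acf_peaks(d)
  trs <- find_acf_peaks(-d)
  if (length(pks) == 0 || length(trs) == 0) {
    return(list(fold_changes = numeric(0), peak_positions_um = numeric(0),
                trough_positions_um = numeric(0)))
  }
  fc <- vapply(pks, function(p) {
    tr <- trs[which.min(abs(trs - p))]
    profile$raw[p] / profile$raw[tr]
  }, numeric(1))
  list(fold_changes = fc,
       peak_positions_um = profile$positions_um[pks],
       trough_positions_um = profile$positions_um[trs])
}

#' High/low persistence of 20-um kymograph bands
#'
#' Splits a kymograph into adjacent non-overlapping dorsoventral bands
#' (half-open `[k*band_um, (k+1)*band_um)` from the ventral origin,
#' default 20 um, half the tissue spatial period), lightly blurs the
#' spatial axis (2 um Gaussian) against single-cell movement, z-scores
#' each band's mean time series, and measures the continuous intervals
#' the band spends above (high) or below (low) its mean. First and last
#' intervals are censored (their start/end is unobserved) and excluded
#' from the summary statistics.
#'
#' @param kymo a [kymograph()].
#' @param band_um band width, micrometres (default 20).
#' @param blur_um Gaussian blur SD along the spatial axis (default 2).
#' @param mode `"mean_crossing"` (default) scores intervals by sign of
#'   the z-scored band series; `"zero_crossing"` seeds high/low regions
#'   from the first two hours of the record and then scores crossings.
#' @return An object of class `"persistence_result"`: per-band list with
#'   `band_start_um`, `high_intervals_h`, `low_intervals_h`, and summary
#'   vectors `high_h`, `low_h` (censored intervals dropped),
#'   `persistence_ratio` per band (mean high / mean low, NA when a state
#'   is unobserved), `band_series` (z-scored matrix bands x time).
#' @export
band_persistence <- function(kymo, band_um = 20, blur_um = 2,
                             mode = c("mean_crossing", "zero_crossing")) {
  stopifnot(inherits(kymo, "kymograph"))
  mode <- match.arg(mode)
  if (band_um > max(kymo$positions_um) + kymo$um_per_bin) {
    stop("band wider than the spatial domain", call. = FALSE)
  }
  if (diff(range(kymo$times_min)) < 240) stop("record shorter than 4 h", call. = FALSE)
  mat <- gauss_blur_rows(kymo$mat, blur_um / kymo$um_per_bin)
  if (mode == "mean_crossing") {
    band_id <- floor(kymo$positions_um / band_um)
  } else {
    # regions seeded from the sign of the detrended 0-2 h spatial profile
    first2h <- which(kymo$times_min - kymo$times_min[1] < 120)
    prof <- detrend_spatial(rowMeans(mat[, first2h, drop = FALSE]),
                            kymo$positions_um)$detrended
    runs <- rle(prof >= 0)
    band_id <- rep(seq_along(runs$lengths), runs$lengths) - 1L
  }
  bands <- sort(unique(band_id))
  series <- t(vapply(bands, function(b) {
    colMeans(mat[band_id == b, , drop = FALSE])
  }, numeric(ncol(mat))))
  zs <- t(apply(series, 1, function(x) {
    s <- stats::sd(x); if (s == 0) x * 0 else (x - mean(x)) / s
  }))
  dt_h <- kymo$min_per_frame / 60
  band_origin <- vapply(bands, function(b) min(kymo$positions_um[band_id == b]),
                        numeric(1))
  per_band <- lapply(seq_along(bands), function(i) {
    state <- zs[i, ] >= 0
    r <- rle(state)
    dur <- r$lengths * dt_h
    k <- length(dur)
    censored <- if (k >= 2) c(TRUE, rep(FALSE, k - 2), TRUE) else rep(TRUE, k)
    list(band_start_um = band_origin[i],
         high_intervals_h = dur[r$values & !censored],
         low_intervals_h = dur[!r$values & !censored],
         all_high_h = dur[r$values], all_low_h = dur[!r$values])
  })
  high_h <- unlist(lapply(per_band, `[[`, "high_intervals_h"))
  low_h <- unlist(lapply(per_band, `[[`, "low_intervals_h"))
  ratio <- vapply(per_band, function(b) {
    if (length(b$high_intervals_h) && length(b$low_intervals_h)) {
      mean(b$high_intervals_h) / mean(b$low_intervals_h)
    } else NA_real_
  }, numeric(1))
  structure(list(bands = per_band, high_h = high_h, low_h = low_h,
                 persistence_ratio = ratio, band_series = zs,
                 band_start_um = band_origin, mode = mode),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf("Band persistence (%s): %d bands\n", x$mode, length(x$bands)))
  if (length(x$high_h)) cat(sprintf("  high: median %.1f h (n = %d)\n",
                                    stats::median(x$high_h), length(x$high_h)))
  if (length(x$low_h)) cat(sprintf("  low:  median %.1f h (n = %d)\n",
                                   stats::median(x$low_h), length(x$low_h)))
  invisible(x)
}

# Gaussian blur along rows (spatial axis) with SD in bins; reflective ends
gauss_blur_rows <- function(mat, sd_bins) {
  if (sd_bins <= 0) return(mat)
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- stats::dnorm(-half:half, sd = sd_bins)
  kern <- kern / sum(kern)
  n <- nrow(mat)
  idx <- seq_len(n)
  pad <- c(rev(idx[seq_len(min(half, n))]), idx, rev(idx)[seq_len(min(half, n))])
  padded <- mat[pad, , drop = FALSE]
  out <- apply(padded, 2, function(col) {
    as.vector(stats::filter(col, kern, sides = 2))
  })
  out[(half + 1):(half + n), , drop = FALSE]
}

#' Hierarchical clustering of kymograph bands
#'
#' Average-linkage hierarchical clustering of z-scored 20-um band time
#' series on Euclidean distances, as used to order band heatmaps and
#' reveal low-to-high / high-to-low switching groups.
#'
#' @param band_zscores numeric matrix, bands x timepoints (>= 3 bands),
#'   e.g. the `band_series` of [band_persistence()].
#' @return List with `hclust` (the tree), `order` (leaf order),
#'   `ordered` (the reordered matrix), `cophenetic` (distance matrix).
#' @export
cluster_bands <- function(band_zscores) {
  m <- as.matrix(band_zscores)
  if (nrow(m) < 3) stop("need at least 3 bands to cluster", call. = FALSE)
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = hc$order,
       ordered = m[hc$order, , drop = FALSE],
       cophenetic = stats::cophenetic(hc))
}

#' Spatiotemporal phase map of a kymograph
#'
#' Averages the kymograph over consecutive timeblocks (default 2 h),
#' detrends each block's spatial profile (polynomial order 4), smooths it
#' (Savitzky-Golay) and reconstructs the spatial phase along the
#' dorsoventral axis by the Hilbert transform. Columns are timeblocks;
#' phase resets along a row reveal high/low switching at that position.
#' Blocks with a degenerate profile are flagged invalid; each block also
#' carries a spatial-periodicity flag from [spatial_autocorr()] so that
#' downstream synchrony scores can be restricted to periodic epochs.
#'
#' @param kymo a [kymograph()].
#' @param block_h timeblock length, hours (default 2).
#' @param poly_order detrend order per block (default 4).
#' @param check_periodicity run the bootstrap periodicity test per block
#'   (default TRUE).
#' @param n_boot,seed bootstrap settings for the per-block test.
#' @return An object of class `"phase_map"`: `phase` (positions x
#'   blocks, radians), `valid`, `periodic` (logical per block, NA when
#'   not tested), `block_times_h`, `positions_um`.
#' @export
phase_map <- function(kymo, block_h = 2, poly_order = 4,
                      check_periodicity = TRUE, n_boot = 100, seed = 1L) {
  stopifnot(inherits(kymo, "kymograph"))
  block_min <- block_h * 60
  blocks <- floor((kymo$times_min - kymo$times_min[1]) / block_min)
  nb <- max(blocks) + 1L
  if (nb < 2) stop("record shorter than 2 timeblocks", call. = FALSE)
  npos <- nrow(kymo$mat)
  ph <- matrix(NA_real_, npos, nb)
  valid <- logical(nb)
  periodic <- rep(NA, nb)
  for (b in seq_len(nb) - 1L) {
    prof <- rowMeans(kymo$mat[, blocks == b, drop = FALSE])
    ok <- tryCatch({
      sp <- detrend_spatial(prof, kymo$positions_um, poly_order)
      sm <- sg_smooth(sp$detrended, 5, 2)
      ph[, b + 1L] <- analytic_phase(sm, taper = 0)$phase
      if (check_periodicity) {
        acr <- spatial_autocorr(sp, um_per_bin = kymo$um_per_bin,
                                n_boot = n_boot, seed = seed + b)
        periodic[b + 1L] <- acr$is_periodic
      }
      TRUE
    }, error = function(e) FALSE)
    valid[b + 1L] <- ok
  }
  structure(list(phase = ph, valid = valid, periodic = periodic,
                 block_times_h = (seq_len(nb) - 0.5) * block_h,
                 positions_um = kymo$positions_um),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Phase map: %d D-V positions x %d timeblocks (%d valid",
              nrow(x$phase), ncol(x$phase), sum(x$valid)))
  if (!all(is.na(x$periodic))) cat(sprintf(", %d periodic", sum(x$periodic, na.rm = TRUE)))
  cat(")\n")
  invisible(x)
}

#' Anterior-posterior correlation of detrended profiles
#'
#' Pearson correlation between detrended dorsoventral profiles taken at
#' known anterior-posterior offsets (successive z-stacks), quantifying
#' how far the micro-pattern extends along the A-P axis.
#'
#' @param profiles numeric matrix, one detrended profile per column, all
#'   on the same dorsoventral grid.
#' @param ap_positions_um anterior-posterior position of each profile.
#' @return Data frame with one row per profile pair: `i`, `j`,
#'   `distance_um`, `r`.
#' @export
ap_correlation <- function(profiles, ap_positions_um) {
  m <- as.matrix(profiles)
  if (ncol(m) < 2) stop("need at least two profiles", call. = FALSE)
  if (length(ap_positions_um) != ncol(m)) {
    stop("one A-P position per profile required", call. = FALSE)
  }
  pairs <- utils::combn(ncol(m), 2)
  data.frame(
    i = pairs[1, ], j = pairs[2, ],
    distance_um = abs(ap_positions_um[pairs[2, ]] - ap_positions_um[pairs[1, ]]),
    r = apply(pairs, 2, function(p) stats::cor(m[, p[1]], m[, p[2]]))
  )
}

#' Split a profile or kymograph into motorneuron and interneuron domains
#'
#' The motorneuron (MN) / interneuron (IN) boundary is placed 35 um
#' ventral of the peak of the HES5 dorsoventral trend (the offset at
#' which the trend peak sits dorsal to the edge of the OLIG2-positive
#' domain). The ventral segment is labelled MN and the dorsal segment IN.
#'
#' @param x a `"spatial_profile"` or a [kymograph()] (the trend is then
#'   taken from the time-averaged profile).
#' @param offset_um boundary offset ventral of the trend peak (default
#'   35).
#' @param poly_order trend order when `x` is a kymograph.
#' @return List with `boundary_um` and `mn`, `in_` index vectors into the
#'   dorsoventral axis; `NULL` (with a warning) when the trend peak sits
#'   at the domain edge.
#' @export
split_mn_in <- function(x, offset_um = 35, poly_order = 4) {
  if (inherits(x, "kymograph")) {
    x <- detrend_spatial(rowMeans(x$mat), x$positions_um, poly_order)
  }
  stopifnot(inherits(x, "spatial_profile"))
  pk <- which.max(x$trend)
  if (pk == 1L || pk == length(x$trend)) {
    warning("trend peak at domain edge: no MN/IN split")
    return(NULL)
  }
  boundary <- x$positions_um[pk] - offset_um
  mn <- which(x$positions_um < boundary)
  dorsal <- which(x$positions_um >= boundary)
  if (length(mn) == 0) {
    warning("boundary falls ventral of the domain: no MN/IN split")
    return(NULL)
  }
  list(boundary_um = boundary, mn = mn, in_ = dorsal)
}
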