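#' Synthetic nucleus field with planted microclusters and gradient
#'
#' Generates a jittered hexagonally packed field of nuclei whose
#' intensities are built from known ground truth: a baseline, planted
#' high-intensity microclusters repeating along the dorsoventral axis
#' with a chosen spatial period, Gaussian noise, and a radial gradient
#' `I_r = Z + alpha * x_r` away from a focal point. The recorded truth
#' sidecar lets recovery tests compare detected structure against what
#' was planted.
#'
#' @param n_cells approximate number of nuclei (layout is a hexagonal
#'   grid with dorsoventral extent about twice the apical-basal one).
#' @param pitch_um nuclear pitch, micrometres (default 10).
#' @param jitter_um SD of centroid jitter (default 0.5).
#' @param cluster_size target cells per planted microcluster (default 4;
#'   0 disables clusters).
#' @param period_um dorsoventral repeat of the planted clusters
#'   (default 40; must be >= 2 * pitch).
#' @param baseline baseline intensity (default 100).
#' @param cluster_amp added intensity inside clusters (default 100,
#'   placing cluster cells in a brighter geometric bin).
#' @param noise_sd Gaussian intensity noise SD (default 0).
#' @param alpha radial gradient strength, intensity per um (default 0).
#' @param seed RNG seed.
#' @return List with `table` (a [nucleus_table()]) and `truth`
#'   (`planted_period_um`, `planted_cluster_members` list,
#'   `alpha_gradient`, `seed`, layout fields).
#' @export
synth_nucleus_field <- function(n_cells = 300, pitch_um = 10, jitter_um = 0.5,
                                cluster_size = 4, period_um = 40,
                                baseline = 100, cluster_amp = 100,
                                noise_sd = 0, alpha = 0, seed = 1L) {
  if (cluster_size > 0 && period_um < 2 * pitch_um) {
    stop("period_um must be at least two nuclear pitches", call. = FALSE)
  }
  set.seed(seed)
  n_rows <- max(3L, round(sqrt(n_cells / 2)))
  n_cols <- ceiling(n_cells / n_rows)
  rows <- rep(seq_len(n_rows), times = n_cols)
  cols <- rep(seq_len(n_cols), each = n_rows)
  y <- (cols - 1 + 0.5 * (rows %% 2)) * pitch_um
  x <- (rows - 1) * pitch_um * sqrt(3) / 2
  n <- length(x)
  x <- x + stats::rnorm(n, 0, jitter_um)
  y <- y + stats::rnorm(n, 0, jitter_um)

  intensity <- rep(baseline, n)
  members <- list()
  if (cluster_size > 0) {
    w_dv <- ceiling(sqrt(cluster_size))          # cluster extent in DV columns
    w_ab <- ceiling(cluster_size / w_dv)         # and in AB rows
    ab_rows <- seq_len(w_ab) + floor((n_rows - w_ab) / 2)
    period_cols <- max(w_dv + 1, round(period_um / pitch_um))
    starts <- seq(1L, n_cols - w_dv + 1L, by = period_cols)
    for (s in starts) {
      sel <- which(cols %in% (s:(s + w_dv - 1L)) & rows %in% ab_rows)
      sel <- utils::head(sel, cluster_size)
      intensity[sel] <- intensity[sel] + cluster_amp
      members[[length(members) + 1L]] <- sel
    }
  }
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(n, 0, noise_sd)
  if (alpha != 0) {
    # radial gradient from the field centre
    cx <- mean(x); cy <- mean(y)
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    intensity <- intensity + alpha * r
  }
  intensity <- pmax(intensity, 1e-6)
  tab <- nucleus_table(data.frame(
    nucleus_id = seq_len(n), x_um = x, y_um = y, intensity = intensity
  ))
  list(table = tab,
       truth = list(planted_period_um = if (cluster_size > 0) period_cols * pitch_um else NA_real_,
                    planted_cluster_members = members,
                    alpha_gradient = alpha, noise_sd = noise_sd,
                    n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
                    seed = seed))
}

#' Synthetic kymograph with planted period and switching persistence
#'
#' Builds a dorsoventral-position x time kymograph from known truth: a
#' bell-shaped dorsoventral trend, a spatial cosine of chosen period
#' whose half-period bands independently flip between high and low
#' states as telegraph processes with a chosen mean dwell time, plus
#' white noise.
#'
#' @param length_um dorsoventral extent (default 200).
#' @param duration_h record length, hours (default 24).
#' @param um_per_bin spatial sampling (default 2).
#' @param min_per_frame temporal sampling (default 15).
#' @param period_um planted spatial period (default 40).
#' @param trend_amp amplitude of the bell-shaped trend (default 200; 0
#'   disables).
#' @param pattern_amp amplitude of the periodic pattern (default 50).
#' @param switch_persistence_h mean telegraph dwell per band, hours
#'   (`Inf` freezes the pattern; default `Inf`).
#' @param noise_sd white-noise SD (default 0).
#' @param seed RNG seed.
#' @return List with `kymo` (a [kymograph()]) and `truth`.
#' @export
synth_kymograph <- function(length_um = 200, duration_h = 24, um_per_bin = 2,
                            min_per_frame = 15, period_um = 40,
                            trend_amp = 200, pattern_amp = 50,
                            switch_persistence_h = Inf, noise_sd = 0,
                            seed = 1L) {
  if (is.finite(switch_persistence_h) && duration_h < 2 * switch_persistence_h) {
    stop("duration must cover at least two mean dwell times", call. = FALSE)
  }
  set.seed(seed)
  pos <- seq(0, length_um - um_per_bin, by = um_per_bin)
  tms <- seq(0, duration_h * 60 - min_per_frame, by = min_per_frame)
  np <- length(pos); nt <- length(tms)
  trend <- trend_amp * exp(-((pos - length_um / 2)^2) / (2 * (length_um / 4)^2))
  # sine so the positive/negative lobes tile half-open half-period bands
  # starting at the ventral origin, matching the telegraph blocks
  wave <- sin(2 * pi * pos / period_um)
  band <- floor(pos / (period_um / 2))
  nb <- max(band) + 1L
  sign_mat <- matrix(1, nb, nt)
  if (is.finite(switch_persistence_h)) {
    p_flip <- min_per_frame / 60 / switch_persistence_h  # per-frame flip prob
    for (b in seq_len(nb)) {
      s <- numeric(nt); cur <- 1
      flips <- stats::runif(nt) < p_flip
      for (k in seq_len(nt)) { if (flips[k]) cur <- -cur; s[k] <- cur }
      sign_mat[b, ] <- s
    }
  }
  mat <- matrix(trend, np, nt) +
    pattern_amp * wave * sign_mat[band + 1L, , drop = FALSE]
  if (noise_sd > 0) mat <- mat + matrix(stats::rnorm(np * nt, 0, noise_sd), np)
  list(kymo = kymograph(mat, um_per_bin, min_per_frame),
       truth = list(planted_period_um = period_um,
                    switching_persistence_h = switch_persistence_h,
                    trend_amp = trend_amp, pattern_amp = pattern_amp,
                    noise_sd = noise_sd, seed = seed))
}

#' Synthetic phase-locked oscillator pair
#'
#' Two sinusoidal single-cell traces with a shared slow trend, additive
#' noise and a specified phase lag, emulating neighbouring cell pairs
#' with locally synchronised ultradian dynamics.
#'
#' @param period_h oscillation period, hours (default 3.3).
#' @param phase_lag_rad phase of trace b relative to a, radians
#'   (default 0).
#' @param trend_amp amplitude of the shared slow trend (default 0).
#' @param noise_sd additive noise SD (default 0).
#' @param duration_h record length (default 12; must be >= 3 periods).
#' @param dt_min sampling interval, min (default 15).
#' @param seed RNG seed.
#' @return List with `times_min`, `a`, `b`, `truth`.
#' @export
synth_oscillator_pair <- function(period_h = 3.3, phase_lag_rad = 0,
                                  trend_amp = 0, noise_sd = 0,
                                  duration_h = 12, dt_min = 15, seed = 1L) {
  if (duration_h < 3 * period_h) {
    stop("duration must cover at least three periods", call. = FALSE)
  }
  set.seed(seed)
  t <- seq(0, duration_h * 60, by = dt_min)
  w <- 2 * pi / (period_h * 60)
  trend <- trend_amp * sin(2 * pi * t / (duration_h * 60 * 2))
  a <- trend + sin(w * t) + stats::rnorm(length(t), 0, noise_sd)
  b <- trend + sin(w * t - phase_lag_rad) + stats::rnorm(length(t), 0, noise_sd)
  list(times_min = t, a = a, b = b,
       truth = list(period_h = period_h, pair_phase_lag_rad = phase_lag_rad,
                    trend_amp = trend_amp, noise_sd = noise_sd, seed = seed))
}
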