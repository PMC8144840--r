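#' Repressive Hill function
#'
#' The monotone decreasing Hill function `1 / (1 + (level/threshold)^hill)`
#' used both for HES5 auto-repression (intra-cellular, G) and for
#' Notch-Delta repression by the neighbour-mean protein level
#' (inter-cellular, J). Returns 1 with no repressor and 1/2 at the
#' threshold. An infinite threshold returns 1 everywhere (coupling off).
#'
#' @param level repressor abundance (molecules), >= 0; vectorised.
#' @param threshold half-maximal repression level (molecules), > 0.
#' @param hill Hill coefficient, >= 1.
#' @return Rate multiplier in (0, 1].
#' @export
#' @examples
#' hill_repression(0, 100, 4)          # 1
#' hill_repression(100, 100, 4)        # 0.5
#' hill_repression(200, 100, 4)        # 1/17
hill_repression <- function(level, threshold, hill) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0) {
    stop("threshold must be a positive number (Inf allowed)", call. = FALSE)
  }
  if (!is.finite(hill) || hill < 1) stop("hill must be >= 1", call. = FALSE)
  if (any(level < 0, na.rm = TRUE)) stop("level must be >= 0", call. = FALSE)
  if (is.infinite(threshold)) return(rep(1, length(level)))
  1 / (1 + (level / threshold)^hill)
}

#' Deterministic steady state of the uncoupled single-cell model
#'
#' Solves the fixed point of the noise-free, uncoupled system
#' `mu_m m = alpha_m G(p)`, `mu_p p = alpha_p m`. Because `G` is strictly
#' decreasing the scalar fixed-point equation has a unique root, found by
#' bisection.
#'
#' @param scp a [single_cell_params()] object.
#' @return Named numeric `c(mrna, protein)`.
#' @export
steady_state <- function(scp) {
  stopifnot(inherits(scp, "single_cell_params"))
  C <- scp$transcription_rate_max * scp$translation_rate /
    (scp$mrna_degradation * scp$protein_degradation)
  # root of f(p) = C * G(p) - p, decreasing from C at p = 0
  f <- function(p) C * hill_repression(p, scp$autorepression_threshold,
                                       scp$autorepression_hill) - p
  p_star <- stats::uniroot(f, interval = c(0, C), tol = 1e-10 * max(C, 1))$root
  m_star <- scp$protein_degradation * p_star / scp$translation_rate
  c(mrna = m_star, protein = p_star)
}

#' Simulate coupled HES5 dynamics on a hexagonal lattice
#'
#' Euler-Maruyama integration of the delayed chemical-Langevin model.
#' Per cell i, with `G` the intra-cellular and `J` the inter-cellular
#' repressive Hill function and `pbar_i(t)` the mean protein over the
#' cell's hexagonal neighbours:
#'
#' \deqn{dm_i = [\alpha_m G(p_i(t-\tau_H)) J(\bar p_i(t-\tau_{ND})) -
#'   \mu_m m_i] dt + \sqrt{\alpha_m G J + \mu_m m_i}\, dW_m}
#' \deqn{dp_i = [\alpha_p m_i - \mu_p p_i] dt +
#'   \sqrt{\alpha_p m_i + \mu_p p_i}\, dW_p}
#'
#' The two repressive inputs act multiplicatively on the transcription
#' rate, preserving the half-max semantics of each Hill function.
#' Abundances are clipped at zero each step (standard chemical-Langevin
#' practice). Identical seeds give identical trajectories.
#'
#' @param scp [single_cell_params()].
#' @param cp [coupling_params()]; `repression_threshold_p0 = Inf` disables
#'   coupling.
#' @param lattice [hex_lattice()].
#' @param config [sim_config()].
#' @return An object of class `"hes_sim"`: list with `times` (min,
#'   0 = end of burn-in), `protein` and `mrna` (`n_cells x n_times`
#'   matrices), `lattice`, `scp`, `cp`, `config`, `seed`.
#' @export
#' @examples
#' lat <- hex_lattice(4, 6)
#' sim <- simulate_hes5(single_cell_params(), coupling_params(400),
#'                      lat, sim_config(t_end = 900, burn_in = 300, seed = 7))
#' dim(sim$protein)
simulate_hes5 <- function(scp, cp, lattice, config) {
  stopifnot(inherits(scp, "single_cell_params"), inherits(cp, "coupling_params"),
            inherits(lattice, "hex_lattice"), inherits(config, "sim_config"))
  dt <- config$dt
  if (dt > min(1 / scp$mrna_degradation, 1 / scp$protein_degradation)) {
    warning("dt exceeds the fastest degradation timescale; integration may be inaccurate")
  }
  d_h <- delay_steps(scp$transcription_delay_tau_h, dt, "transcription delay")
  d_nd <- delay_steps(cp$intercellular_delay_tau_nd, dt, "inter-cellular delay")
  coupled <- is.finite(cp$repression_threshold_p0)
  d_max <- max(d_h, if (coupled) d_nd else 0L, 1L)

  n <- lattice$n_cells
  n_steps <- ceiling(config$t_end / dt)
  rec_stride <- as.integer(round(config$record_every / dt))
  rec_steps <- seq.int(ceiling(config$burn_in / dt), n_steps, by = rec_stride)

  # neighbour bookkeeping: flat index matrix + per-cell neighbour count
  nbr <- lattice$neighbors
  nbr_count <- rowSums(!is.na(nbr))
  nbr_filled <- nbr
  nbr_filled[is.na(nbr)] <- 1L  # placeholder; masked by zero weight below
  nbr_w <- (!is.na(nbr)) * 1

  set.seed(config$seed)
  ss <- steady_state(scp)
  init <- switch(config$history_init,
    steady_state = list(m = rep(ss["mrna"], n), p = rep(ss["protein"], n)),
    perturbed = {
      cv <- config$history_jitter
      sdl <- sqrt(log(1 + cv^2))
      jit <- exp(stats::rnorm(n, -sdl^2 / 2, sdl))
      list(m = ss["mrna"] * jit, p = ss["protein"] * jit)
    },
    constant = list(m = rep(config$history_value[1], n),
                    p = rep(config$history_value[2], n))
  )

  # protein history buffer: columns 1..d_max hold the (constant) pre-history
  P <- matrix(0, n, n_steps + d_max + 1L)
  P[, seq_len(d_max + 1L)] <- init$p
  m <- init$m
  p <- init$p

  noise <- scp$noise_enabled
  a_m <- scp$transcription_rate_max; a_p <- scp$translation_rate
  mu_m <- scp$mrna_degradation; mu_p <- scp$protein_degradation
  sq_dt <- sqrt(dt)

  rec_p <- matrix(0, n, length(rec_steps))
  rec_m <- matrix(0, n, length(rec_steps))
  rec_at <- integer(n_steps + 1L); rec_at[] <- 0L
  rec_at[rec_steps + 1L] <- seq_along(rec_steps)
  if (rec_at[1L] > 0L) { rec_p[, rec_at[1L]] <- p; rec_m[, rec_at[1L]] <- m }

  for (k in seq_len(n_steps)) {
    now <- d_max + k  # column of P holding state at step k-1
    p_tau_h <- P[, now - d_h]
    G <- hill_repression(p_tau_h, scp$autorepression_threshold,
                         scp$autorepression_hill)
    if (coupled) {
      p_tau_nd <- P[, now - d_nd]
      pbar <- (matrix(p_tau_nd[nbr_filled], n, 6L) * nbr_w) %*% rep(1, 6L)
      pbar <- as.vector(pbar) / nbr_count
      J <- hill_repression(pbar, cp$repression_threshold_p0, cp$hill_coefficient_n)
    } else {
      J <- 1
    }
    prod_m <- a_m * G * J
    dm <- (prod_m - mu_m * m) * dt
    dp <- (a_p * m - mu_p * p) * dt
    if (noise) {
      dm <- dm + sqrt(pmax(prod_m + mu_m * m, 0)) * sq_dt * stats::rnorm(n)
      dp <- dp + sqrt(pmax(a_p * m + mu_p * p, 0)) * sq_dt * stats::rnorm(n)
    }
    m <- pmax(m + dm, 0)
    p <- pmax(p + dp, 0)
    P[, now + 1L] <- p
    ri <- rec_at[k + 1L]
    if (ri > 0L) { rec_p[, ri] <- p; rec_m[, ri] <- m }
  }

  structure(list(
    times = rec_steps * dt - config$burn_in,
    protein = rec_p, mrna = rec_m,
    lattice = lattice, scp = scp, cp = cp, config = config,
    seed = config$seed
  ), class = "hes_sim")
}

delay_steps <- function(tau, dt, what) {
  k <- round(tau / dt)
  if (abs(k * dt - tau) > 1e-9) {
    warning(sprintf("%s (%g min) rounded to %g min on the dt grid", what, tau, k * dt))
  }
  as.integer(k)
}

#' @export
print.hes_sim <- function(x, ...) {
  cat(sprintf("HES5 lattice simulation: %d cells (%d x %d), %d frames every %g min\n",
              x$lattice$n_cells, x$lattice$n_rows, x$lattice$n_cols,
              ncol(x$protein), x$config$record_every))
  p0 <- x$cp$repression_threshold_p0
  cat(sprintf("  coupling: %s, seed %d\n",
              if (is.finite(p0)) sprintf("P0 = %.4g", p0) else "off", x$seed))
  cat(sprintf("  mean protein %.4g molecules (CoV %.2f)\n",
              mean(x$protein), stats::sd(x$protein) / mean(x$protein)))
  invisible(x)
}

#' @export
summary.hes_sim <- function(object, ...) {
  p <- object$protein
  cellm <- rowMeans(p)
  out <- list(
    n_cells = nrow(p), n_frames = ncol(p),
    mean_protein = mean(p),
    temporal_cov = mean(apply(p, 1, stats::sd) / cellm),
    spatial_cov = mean(apply(p, 2, stats::sd) / colMeans(p))
  )
  class(out) <- "summary.hes_sim"
  out
}

#' @export
print.summary.hes_sim <- function(x, ...) {
  cat(sprintf("%d cells x %d frames; mean protein %.4g\n",
              x$n_cells, x$n_frames, x$mean_protein))
  cat(sprintf("temporal CoV %.3f, spatial CoV %.3f\n",
              x$temporal_cov, x$spatial_cov))
  invisible(x)
}

#' @export
#' @importFrom graphics matplot
plot.hes_sim <- function(x, cells = seq_len(min(5L, nrow(x$protein))), ...) {
  matplot(x$times / 60, t(x$protein[cells, , drop = FALSE]), type = "l",
          lty = 1, xlab = "Time (h)", ylab = "HES5 protein (molecules)", ...)
  invisible(x)
}

#' Kymograph of a lattice simulation
#'
#' Collapses the apical-basal (row) dimension of the protein field by
#' averaging, leaving a dorsoventral position x time intensity matrix.
#' Column 1 of the lattice is the ventral-most bin; the spatial
#' calibration is the lattice cell pitch.
#'
#' @param sim a `"hes_sim"` from [simulate_hes5()].
#' @return A [kymograph()], one row per dorsoventral cell column.
#' @export
model_kymograph <- function(sim) {
  stopifnot(inherits(sim, "hes_sim"))
  lat <- sim$lattice
  km <- matrix(0, lat$n_cols, ncol(sim$protein))
  for (cc in seq_len(lat$n_cols)) {
    km[cc, ] <- colMeans(sim$protein[lat$col == cc, , drop = FALSE])
  }
  kymograph(km, um_per_bin = lat$cell_pitch_um,
            min_per_frame = sim$config$record_every)
}
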