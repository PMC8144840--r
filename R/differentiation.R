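#' Differentiation-probability model parameters
#'
#' Differentiation is modelled as a hazard that switches on when a
#' cell's HES5 protein drops below a differentiation threshold set at
#' the population mean of the simulation. The hazard grows linearly
#' with the relative deficit below the threshold:
#' `lambda(t) = k * max(0, (D_thresh - P(t)) / D_thresh)`, so a cell at
#' half the threshold differentiates at rate `k/2`. The linear-deficit
#' form is the minimal choice consistent with a rate that increases as
#' protein falls below the mean; an alternative hazard can be plugged
#' in via `hazard_fn`.
#'
#' @param hazard_scale_k hazard scale, 1/min (default 1e-3, chosen so an
#'   uncoupled population loses on the order of a few percent of cells
#'   per 10 h).
#' @param hazard_fn optional function `(protein, d_thresh)` returning
#'   hazards in 1/min; overrides the linear-deficit form.
#' @return An object of class `"differentiation_params"`.
#' @export
differentiation_params <- function(hazard_scale_k = 1e-3, hazard_fn = NULL) {
  if (!is.finite(hazard_scale_k) || hazard_scale_k <= 0) {
    stop("hazard_scale_k must be > 0", call. = FALSE)
  }
  if (!is.null(hazard_fn) && !is.function(hazard_fn)) {
    stop("hazard_fn must be a function(protein, d_thresh)", call. = FALSE)
  }
  structure(list(hazard_scale_k = hazard_scale_k, hazard_fn = hazard_fn,
                 threshold_mode = "population_mean"),
            class = "differentiation_params")
}

#' Differentiation threshold of a simulation
#'
#' The population-mean HES5 protein level over all cells and all
#' recorded (post-burn-in) timepoints of a simulation.
#'
#' @param sim a `"hes_sim"` from [simulate_hes5()], or a numeric matrix
#'   of protein levels (cells x timepoints).
#' @return Scalar threshold, molecules.
#' @export
differentiation_threshold <- function(sim) {
  p <- if (inherits(sim, "hes_sim")) sim$protein else as.matrix(sim)
  if (length(p) == 0) stop("empty protein record", call. = FALSE)
  mean(p)
}

#' Simulate differentiation events on recorded trajectories
#'
#' Applies the differentiation hazard to each cell's recorded protein
#' trace. Per recording step, a not-yet-differentiated cell fires with
#' probability `1 - exp(-lambda * dt)`; fired cells are censored (they
#' stop contributing cell-time at risk). The differentiation rate is
#' events per cell per hour of time at risk.
#'
#' @param sim a `"hes_sim"`.
#' @param params a [differentiation_params()].
#' @param seed RNG seed for the event draws.
#' @return List with `events` data frame (`cell`, `time_min`),
#'   `diff_rate_per_cell_h`, `d_thresh`, `n_cells`, `cell_hours_at_risk`.
#' @export
simulate_differentiation <- function(sim, params = differentiation_params(),
                                     seed = 1L) {
  stopifnot(inherits(sim, "hes_sim"), inherits(params, "differentiation_params"))
  p <- sim$protein
  dt <- diff(sim$times[1:2])
  k <- params$hazard_scale_k
  if (k * dt > 0.5) {
    warning("hazard_scale_k * recording step > 0.5: hazard discretisation is coarse")
  }
  d_thresh <- differentiation_threshold(sim)
  lam <- if (is.null(params$hazard_fn)) {
    k * pmax(0, (d_thresh - p) / d_thresh)
  } else {
    params$hazard_fn(p, d_thresh)
  }
  set.seed(seed)
  fire_p <- 1 - exp(-lam * dt)
  u <- matrix(stats::runif(length(p)), nrow(p))
  fired <- u < fire_p
  # first firing step per cell (NA if never)
  first <- apply(fired, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  events <- data.frame(cell = which(!is.na(first)),
                       time_min = sim$times[first[!is.na(first)]])
  steps_at_risk <- ifelse(is.na(first), ncol(p), first)
  cell_hours <- sum(steps_at_risk) * dt / 60
  list(events = events,
       diff_rate_per_cell_h = nrow(events) / cell_hours,
       d_thresh = d_thresh, n_cells = nrow(p),
       cell_hours_at_risk = cell_hours)
}

#' Differentiation rate and variability across a coupling-strength sweep
#'
#' Runs replicate lattice simulations across a grid of inter-cellular
#' repression thresholds (decreasing coupling strength), estimates the
#' differentiation rate on each, and summarises temporal and spatial
#' coefficients of variation of the protein field. Temporal CoV is the
#' per-cell SD/mean over time averaged over cells; spatial CoV is the
#' across-cell SD/mean per timepoint averaged over timepoints.
#'
#' @param scp [single_cell_params()].
#' @param lattice [hex_lattice()].
#' @param config [sim_config()] template; each replicate reseeds from
#'   `seed`.
#' @param p0_grid repression thresholds to sweep (molecules).
#' @param params [differentiation_params()].
#' @param reps replicates per threshold (default 10).
#' @param seed base RNG seed.
#' @param hill_coefficient_n,intercellular_delay_tau_nd coupling
#'   parameters held fixed across the sweep.
#' @return Data frame of class `"diff_rate_result"`: one row per
#'   threshold with `repression_threshold`, `rate_mean`, `rate_sd`,
#'   `temporal_cov`, `spatial_cov`, `n_replicates`.
#' @export
sweep_coupling <- function(scp, lattice, config, p0_grid,
                           params = differentiation_params(), reps = 10,
                           seed = 1L, hill_coefficient_n = 4,
                           intercellular_delay_tau_nd = 150) {
  stopifnot(inherits(scp, "single_cell_params"), inherits(lattice, "hex_lattice"),
            inherits(config, "sim_config"))
  rows <- lapply(seq_along(p0_grid), function(i) {
    cp <- coupling_params(p0_grid[i], hill_coefficient_n,
                          intercellular_delay_tau_nd)
    per_rep <- vapply(seq_len(reps), function(r) {
      cfg <- config
      cfg$seed <- as.integer(seed + 1000L * i + r)
      sim <- simulate_hes5(scp, cp, lattice, cfg)
      s <- summary(sim)
      dd <- simulate_differentiation(sim, params, seed = cfg$seed + 1L)
      c(rate = dd$diff_rate_per_cell_h, tcov = s$temporal_cov,
        scov = s$spatial_cov)
    }, c(rate = 0, tcov = 0, scov = 0))
    data.frame(repression_threshold = p0_grid[i],
               rate_mean = mean(per_rep["rate", ]),
               rate_sd = stats::sd(per_rep["rate", ]),
               temporal_cov = mean(per_rep["tcov", ]),
               spatial_cov = mean(per_rep["scov", ]),
               n_replicates = reps)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diff_rate_result", "data.frame")
  out
}
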