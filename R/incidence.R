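#' Nucleus table from a simulation snapshot
#'
#' Converts one recorded frame of a lattice simulation into a
#' segmented-nucleus table (cell centroids at the lattice coordinates,
#' protein abundance as intensity), the bridge between the simulator and
#' the microcluster analyses.
#'
#' @param sim a `"hes_sim"`.
#' @param frame frame index (default: last).
#' @return A [nucleus_table()].
#' @export
sim_snapshot_table <- function(sim, frame = ncol(sim$protein)) {
  stopifnot(inherits(sim, "hes_sim"))
  lat <- sim$lattice
  nucleus_table(data.frame(
    nucleus_id = seq_len(lat$n_cells),
    x_um = lat$x_um, y_um = lat$y_um,
    intensity = pmax(sim$protein[, frame], 1e-6)
  ))
}

#' Microcluster incidence over a simulation
#'
#' Scores how often in-phase microclusters are present in a simulation:
#' snapshots are taken at a fixed cadence, microclusters detected in the
#' top two intensity bins, and a snapshot counts as cluster-positive
#' when it contains a cluster of at least `min_cells` cells. The
#' incidence is the fraction of positive snapshots; cluster diameters
#' are pooled across snapshots.
#'
#' @param sim a `"hes_sim"`.
#' @param every_min snapshot cadence, min (default 60).
#' @param min_cells minimum cluster size scored (default 3, the smallest
#'   multi-cell grouping beyond the doublets that arise by chance).
#' @param ... passed to [detect_microclusters()].
#' @return List with `incidence`, `n_snapshots`, `n_positive`,
#'   `cluster_sizes`, `dv_diameters_cells`, `ab_diameters_cells`.
#' @export
microcluster_incidence <- function(sim, every_min = 60, min_cells = 3, ...) {
  stopifnot(inherits(sim, "hes_sim"))
  frames <- which((sim$times - sim$times[1]) %% every_min == 0)
  sizes <- integer(0); dv <- integer(0); ab <- integer(0)
  pos <- logical(length(frames))
  for (i in seq_along(frames)) {
    tab <- sim_snapshot_table(sim, frames[i])
    mcs <- detect_microclusters(tab, ...)
    cl <- mcs$clusters
    big <- cl[cl$n_cells >= min_cells, , drop = FALSE]
    pos[i] <- nrow(big) > 0
    sizes <- c(sizes, cl$n_cells)
    dv <- c(dv, big$dv_diameter_cells)
    ab <- c(ab, big$ab_diameter_cells)
  }
  list(incidence = mean(pos), n_snapshots = length(frames),
       n_positive = sum(pos), cluster_sizes = sizes,
       dv_diameters_cells = dv, ab_diameters_cells = ab)
}

#' Spatial period of a simulated protein pattern
#'
#' Measures the dorsoventral spatial period of a lattice simulation the
#' way tissue kymographs are analysed: the model kymograph is averaged
#' over consecutive 2-h timeblocks, each block's profile detrended
#' (order 4) and autocorrelated, and the ACFs averaged over blocks
#' (legitimate because the patterns of interest are stationary on the
#' record). Significant peaks are called against a null built by
#' shuffling each block's detrended profile and averaging identically;
#' the period is the mean spacing of significant peaks.
#'
#' @param sim a `"hes_sim"`.
#' @param block_h averaging block, hours (default 2).
#' @param n_boot shuffle replicates for the null (default 100).
#' @param seed RNG seed for the shuffles.
#' @return List with `period_cells`, `period_um`, `acf` (block-averaged,
#'   lags 1..), `significant_peak_lags_cells`, `envelope`.
#' @export
model_spatial_period <- function(sim, block_h = 2, n_boot = 100, seed = 1L) {
  stopifnot(inherits(sim, "hes_sim"))
  km <- model_kymograph(sim)
  blocks <- floor((km$times_min - km$times_min[1]) / (block_h * 60))
  lag_max <- floor(nrow(km$mat) / 2)
  block_det <- lapply(unique(blocks), function(b) {
    prof <- rowMeans(km$mat[, blocks == b, drop = FALSE])
    detrend_spatial(prof, km$positions_um)$detrended
  })
  mean_acf <- function(profs) {
    rowMeans(vapply(profs, function(d) acf_vec(d, lag_max), numeric(lag_max)))
  }
  a <- mean_acf(block_det)
  set.seed(seed)
  null_a <- replicate(n_boot, mean_acf(lapply(block_det, sample)))
  envelope <- rowMeans(null_a) + 2 * apply(null_a, 1, stats::sd)
  # block averaging already suppresses noise, and the lag axis is short
  # (one bin per cell), so peaks are found on the unsmoothed mean ACF
  pk <- find_acf_peaks(a)
  sig <- pk[a[pk] > envelope[pk]]
  # median spacing, counting the implicit lag-0 peak, resists stray peaks
  p2p <- if (length(sig) >= 1) stats::median(diff(c(0L, sig))) else NA_real_
  list(period_cells = p2p,
       period_um = p2p * sim$lattice$cell_pitch_um,
       acf = a, significant_peak_lags_cells = sig, envelope = envelope)
}
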