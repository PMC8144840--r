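#' Single-cell HES5 model parameters
#'
#' Rate constants, Hill parameters and the transcriptional delay of the
#' intra-cellular HES5 auto-repression loop. All rates are per minute and
#' abundances are molecule counts. The default values (loaded from the
#' package config file `single_cell_params_main.json`) are calibrated so the
#' uncoupled stochastic model reproduces the measured HES5 half-lives
#' (mRNA ~30 min, protein ~90 min), an ultradian period of ~3.3 h and a
#' protein abundance of several tens of thousands of molecules per nucleus.
#'
#' @param transcription_rate_max maximal transcription rate, mRNA/min.
#' @param translation_rate protein produced per mRNA per min.
#' @param mrna_degradation mRNA degradation rate, 1/min.
#' @param protein_degradation protein degradation rate, 1/min.
#' @param autorepression_threshold protein level giving half-maximal
#'   repression of the cell's own transcription (molecules).
#' @param autorepression_hill Hill coefficient of auto-repression (>= 1).
#' @param transcription_delay_tau_h delay between a change in protein and
#'   its effect on own transcription, min.
#' @param noise_enabled logical; include chemical-Langevin noise terms.
#'
#' @return An object of class `"single_cell_params"` (named list).
#' @export
#' @examples
#' scp <- single_cell_params()
#' scp$protein_degradation * 90 / log(2)  # ~1: 90-min protein half-life
single_cell_params <- function(transcription_rate_max = NULL,
                               translation_rate = NULL,
                               mrna_degradation = NULL,
                               protein_degradation = NULL,
                               autorepression_threshold = NULL,
                               autorepression_hill = NULL,
                               transcription_delay_tau_h = NULL,
                               noise_enabled = TRUE) {
  defaults <- default_single_cell_params()
  p <- list(
    transcription_rate_max = transcription_rate_max %||% defaults$transcription_rate_max,
    translation_rate = translation_rate %||% defaults$translation_rate,
    mrna_degradation = mrna_degradation %||% defaults$mrna_degradation,
    protein_degradation = protein_degradation %||% defaults$protein_degradation,
    autorepression_threshold = autorepression_threshold %||% defaults$autorepression_threshold,
    autorepression_hill = autorepression_hill %||% defaults$autorepression_hill,
    transcription_delay_tau_h = transcription_delay_tau_h %||% defaults$transcription_delay_tau_h,
    noise_enabled = isTRUE(noise_enabled)
  )
  validate_single_cell_params(p)
  structure(p, class = "single_cell_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_single_cell_params <- function(p) {
  num <- c("transcription_rate_max", "translation_rate", "mrna_degradation",
           "protein_degradation", "autorepression_threshold",
           "autorepression_hill", "transcription_delay_tau_h")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("single-cell parameter '", f, "' must be a finite number", call. = FALSE)
    }
  }
  pos <- c("transcription_rate_max", "translation_rate", "mrna_degradation",
           "protein_degradation", "autorepression_threshold")
  for (f in pos) {
    if (p[[f]] <= 0) stop("single-cell parameter '", f, "' must be > 0", call. = FALSE)
  }
  if (p$autorepression_hill < 1) stop("autorepression_hill must be >= 1", call. = FALSE)
  if (p$transcription_delay_tau_h < 0) stop("transcription delay must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.single_cell_params <- function(x, ...) {
  cat("Single-cell HES5 parameters:\n")
  cat(sprintf("  transcription (max)   %.4g mRNA/min\n", x$transcription_rate_max))
  cat(sprintf("  translation           %.4g protein/mRNA/min\n", x$translation_rate))
  cat(sprintf("  mRNA half-life        %.3g min\n", log(2) / x$mrna_degradation))
  cat(sprintf("  protein half-life     %.3g min\n", log(2) / x$protein_degradation))
  cat(sprintf("  auto-repression       P0 = %.4g molecules, hill = %.3g\n",
              x$autorepression_threshold, x$autorepression_hill))
  cat(sprintf("  transcription delay   %.4g min\n", x$transcription_delay_tau_h))
  cat(sprintf("  Langevin noise        %s\n", if (x$noise_enabled) "on" else "off"))
  invisible(x)
}

# Shipped defaults; treated purely as config.
default_single_cell_params <- function() {
  path <- system.file("extdata", "single_cell_params_main.json",
                      package = "hespattern", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Inter-cellular (Notch-Delta) coupling parameters
#'
#' Parameters of the delayed inter-cellular Hill function through which the
#' mean HES5 protein level of a cell's six hexagonal neighbours represses
#' its transcription. The repression threshold is the inverse of coupling
#' strength: low `repression_threshold_p0` means little neighbour protein
#' suffices for half-maximal repression (strong coupling), and
#' `repression_threshold_p0 = Inf` disables coupling entirely.
#'
#' @param repression_threshold_p0 neighbour-mean protein level giving
#'   half-maximal repression (molecules); `Inf` encodes "uncoupled".
#' @param hill_coefficient_n steepness of the inter-cellular response
#'   (>= 1); default 4.
#' @param intercellular_delay_tau_nd Notch-Delta transmission delay, min;
#'   default 150.
#'
#' @return An object of class `"coupling_params"`.
#' @export
#' @examples
#' coupling_params(repression_threshold_p0 = 400)   # strong coupling
#' coupling_params(repression_threshold_p0 = Inf)   # uncoupled control
coupling_params <- function(repression_threshold_p0 = 21000,
                            hill_coefficient_n = 4,
                            intercellular_delay_tau_nd = 150) {
  if (!is.numeric(repression_threshold_p0) || length(repression_threshold_p0) != 1L ||
      is.na(repression_threshold_p0) || repression_threshold_p0 <= 0) {
    stop("repression_threshold_p0 must be > 0 (Inf for uncoupled)", call. = FALSE)
  }
  if (!is.finite(hill_coefficient_n) || hill_coefficient_n < 1) {
    stop("hill_coefficient_n must be >= 1", call. = FALSE)
  }
  if (!is.finite(intercellular_delay_tau_nd) || intercellular_delay_tau_nd < 0) {
    stop("intercellular_delay_tau_nd must be >= 0", call. = FALSE)
  }
  structure(list(
    repression_threshold_p0 = repression_threshold_p0,
    hill_coefficient_n = hill_coefficient_n,
    intercellular_delay_tau_nd = intercellular_delay_tau_nd
  ), class = "coupling_params")
}

#' @export
print.coupling_params <- function(x, ...) {
  cat("Inter-cellular coupling parameters:\n")
  if (is.finite(x$repression_threshold_p0)) {
    cat(sprintf("  repression threshold  P0 = %.4g molecules\n", x$repression_threshold_p0))
  } else {
    cat("  repression threshold  Inf (uncoupled)\n")
  }
  cat(sprintf("  Hill coefficient      n = %.3g\n", x$hill_coefficient_n))
  cat(sprintf("  transmission delay    %.4g min\n", x$intercellular_delay_tau_nd))
  invisible(x)
}

#' Simulation configuration
#'
#' Time grid and bookkeeping for the Euler-Maruyama integration of the
#' delayed chemical-Langevin model. Delays are rounded to the nearest
#' multiple of `dt` (with a warning if the rounding is material).
#'
#' @param dt integration step, min (default 1).
#' @param t_end total integrated time, min, including burn-in.
#' @param burn_in initial transient discarded before recording, min.
#' @param record_every recording cadence, min (default 15, the live-imaging
#'   frame interval); must be a multiple of `dt`.
#' @param seed integer RNG seed; the same seed reproduces the trajectory
#'   bit-for-bit.
#' @param history_init one of `"steady_state"` (constant pre-history at the
#'   deterministic uncoupled fixed point), `"perturbed"` (the same with
#'   per-cell lognormal jitter to break lattice symmetry) or `"constant"`
#'   (user value via `history_value`).
#' @param history_jitter coefficient of variation of the lognormal jitter
#'   under `"perturbed"` (default 0.1).
#' @param history_value protein/mRNA pre-history for `"constant"`,
#'   a length-2 numeric `c(mrna, protein)`.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 1, t_end = 3000, burn_in = 600,
                       record_every = 15, seed = 1L,
                       history_init = c("perturbed", "steady_state", "constant"),
                       history_jitter = 0.1,
                       history_value = NULL) {
  history_init <- match.arg(history_init)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (burn_in < 0 || burn_in >= t_end) stop("need 0 <= burn_in < t_end", call. = FALSE)
  if (record_every < dt) stop("record_every must be >= dt", call. = FALSE)
  if (abs(record_every / dt - round(record_every / dt)) > 1e-8) {
    stop("record_every must be a multiple of dt", call. = FALSE)
  }
  if (history_init == "constant" &&
      (is.null(history_value) || length(history_value) != 2L || any(history_value < 0))) {
    stop("history_init = 'constant' needs history_value = c(mrna, protein) >= 0",
         call. = FALSE)
  }
  structure(list(
    dt = dt, t_end = t_end, burn_in = burn_in, record_every = record_every,
    seed = as.integer(seed), history_init = history_init,
    history_jitter = history_jitter, history_value = history_value
  ), class = "sim_config")
}
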