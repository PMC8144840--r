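#' Kymograph container
#'
#' A kymograph is a space x time intensity matrix: rows are dorsoventral
#' position bins (row 1 = ventral-most) and columns are time frames. It is
#' the common currency between the lattice simulator and the spatial
#' statistics: tissue kymographs extracted from live imaging and model
#' kymographs produced by [model_kymograph()] share this container.
#'
#' @param mat numeric matrix, positions x times; no missing values.
#' @param um_per_bin spatial calibration, micrometres per row.
#' @param min_per_frame temporal calibration, minutes per column.
#'
#' @return An object of class `"kymograph"` with fields `mat`,
#'   `positions_um` (bin centres, ventral origin), `times_min`,
#'   `um_per_bin`, `min_per_frame`.
#' @export
kymograph <- function(mat, um_per_bin, min_per_frame) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || anyNA(mat)) {
    stop("kymograph matrix must be numeric with no missing values", call. = FALSE)
  }
  if (!is.finite(um_per_bin) || um_per_bin <= 0 ||
      !is.finite(min_per_frame) || min_per_frame <= 0) {
    stop("calibrations um_per_bin and min_per_frame must be > 0", call. = FALSE)
  }
  structure(list(
    mat = unname(mat),
    positions_um = (seq_len(nrow(mat)) - 1) * um_per_bin,
    times_min = (seq_len(ncol(mat)) - 1) * min_per_frame,
    um_per_bin = um_per_bin,
    min_per_frame = min_per_frame
  ), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d D-V bins (%g um/bin, extent %g um) x %d frames (%g min/frame, %g h)\n",
              nrow(x$mat), x$um_per_bin, nrow(x$mat) * x$um_per_bin,
              ncol(x$mat), x$min_per_frame, ncol(x$mat) * x$min_per_frame / 60))
  cat("  origin: row 1 = ventral-most\n")
  invisible(x)
}

#' @export
#' @importFrom graphics image axis
#' @importFrom grDevices hcl.colors
plot.kymograph <- function(x, main = "Kymograph", ...) {
  image(x = x$times_min / 60, y = x$positions_um, z = t(x$mat),
        col = hcl.colors(64, "viridis"), xlab = "Time (h)",
        ylab = "D-V position (um)", main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Read and write kymographs
#'
#' Kymographs are stored as a delimited (tab-separated) matrix plus a JSON
#' sidecar `<path>.json` holding the calibration
#' (`um_per_bin`, `min_per_frame`, `origin = "ventral"`) and the matrix
#' dimensions, which are checked on read.
#'
#' @param x a [kymograph()].
#' @param path file path of the matrix; the sidecar lives at `<path>.json`.
#' @return `read_kymograph()` returns a [kymograph()];
#'   `write_kymograph()` returns `path` invisibly.
#' @export
write_kymograph <- function(x, path) {
  stopifnot(inherits(x, "kymograph"))
  utils::write.table(x$mat, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(um_per_bin = x$um_per_bin, min_per_frame = x$min_per_frame,
               origin = "ventral", n_positions = nrow(x$mat), n_times = ncol(x$mat))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("kymograph sidecar not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("um_per_bin", "min_per_frame", "n_positions", "n_times")
  if (!all(need %in% names(meta))) {
    stop("kymograph sidecar missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  }
  if (!identical(meta$origin, "ventral")) {
    stop("kymograph sidecar must declare origin = 'ventral'", call. = FALSE)
  }
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  if (nrow(mat) != meta$n_positions || ncol(mat) != meta$n_times) {
    stop(sprintf("kymograph shape %d x %d does not match sidecar %d x %d",
                 nrow(mat), ncol(mat), meta$n_positions, meta$n_times),
         call. = FALSE)
  }
  kymograph(mat, meta$um_per_bin, meta$min_per_frame)
}
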