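#' Hexagonal cell lattice
#'
#' Builds the hexagonal neighbour map on which cells interact. Rows run
#' along the apical-basal axis and columns along the dorsoventral axis;
#' every interior cell touches exactly six neighbours. Odd rows are offset
#' by half a cell pitch, giving the standard "offset coordinate" hexagonal
#' packing. Under a periodic boundary every cell has six neighbours (the
#' row count must then be even so the offset parity closes); under a
#' reflective boundary edge cells keep only their real neighbours and
#' neighbour averages use the actual neighbour count.
#'
#' @param n_rows number of rows (apical-basal extent), >= 2; must be even
#'   when `boundary = "periodic"`.
#' @param n_cols number of columns (dorsoventral extent), >= 2.
#' @param boundary `"periodic"` or `"reflective"`.
#' @param cell_pitch_um centre-to-centre cell distance, micrometres
#'   (default 10, a single-cell width).
#'
#' @return An object of class `"hex_lattice"`: a list with `n_rows`,
#'   `n_cols`, `n_cells`, `boundary`, `cell_pitch_um`, a `n_cells x 6`
#'   integer `neighbors` matrix (NA where a reflective edge cell has fewer
#'   than six), and cell centroid coordinates `x_um` (apical-basal),
#'   `y_um` (dorsoventral, 0 = ventral-most). Cells are indexed
#'   column-major by (row, col): `cell = (col - 1) * n_rows + row`.
#' @export
#' @examples
#' lat <- hex_lattice(4, 6)
#' table(rowSums(!is.na(lat$neighbors)))  # all cells have 6 neighbours
hex_lattice <- function(n_rows, n_cols,
                        boundary = c("periodic", "reflective"),
                        cell_pitch_um = 10) {
  boundary <- match.arg(boundary)
  if (n_rows < 2 || n_cols < 2) {
    stop("lattice must be at least 2 x 2 (1 x N grids are degenerate)", call. = FALSE)
  }
  if (cell_pitch_um <= 0) stop("cell_pitch_um must be > 0", call. = FALSE)
  if (boundary == "periodic" && n_rows %% 2L != 0L) {
    stop("periodic boundary requires an even number of rows", call. = FALSE)
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_cells <- n_rows * n_cols
  idx <- function(r, c) (c - 1L) * n_rows + r

  nbr <- matrix(NA_integer_, n_cells, 6L)
  for (r in seq_len(n_rows)) {
    # odd-row offset coordinates: odd rows shifted +pitch/2 in y
    if (r %% 2L == 1L) {
      dr <- c(0L, 0L, -1L, -1L, 1L, 1L)
      dc <- c(-1L, 1L, 0L, 1L, 0L, 1L)
    } else {
      dr <- c(0L, 0L, -1L, -1L, 1L, 1L)
      dc <- c(-1L, 1L, -1L, 0L, -1L, 0L)
    }
    for (c in seq_len(n_cols)) {
      rr <- r + dr; cc <- c + dc
      if (boundary == "periodic") {
        rr <- ((rr - 1L) %% n_rows) + 1L
        cc <- ((cc - 1L) %% n_cols) + 1L
        nbr[idx(r, c), ] <- idx(rr, cc)
      } else {
        ok <- rr >= 1L & rr <= n_rows & cc >= 1L & cc <= n_cols
        v <- rep(NA_integer_, 6L)
        v[seq_len(sum(ok))] <- idx(rr[ok], cc[ok])
        nbr[idx(r, c), ] <- v
      }
    }
  }

  rows <- rep(seq_len(n_rows), times = n_cols)
  cols <- rep(seq_len(n_cols), each = n_rows)
  y_um <- (cols - 1L + 0.5 * (rows %% 2L)) * cell_pitch_um
  x_um <- (rows - 1L) * cell_pitch_um * sqrt(3) / 2

  structure(list(
    n_rows = n_rows, n_cols = n_cols, n_cells = n_cells,
    boundary = boundary, cell_pitch_um = cell_pitch_um,
    neighbors = nbr, row = rows, col = cols, x_um = x_um, y_um = y_um
  ), class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("Hexagonal lattice: %d rows (A-B) x %d cols (D-V), %s boundary, pitch %g um\n",
              x$n_rows, x$n_cols, x$boundary, x$cell_pitch_um))
  invisible(x)
}
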