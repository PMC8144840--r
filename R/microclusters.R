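#' Segmented-nucleus tables
#'
#' Analyses of nuclear HES5 micro-patterns start from a table of
#' segmented nuclei: one row per nucleus with centroid coordinates
#' (micrometres; `y_um` runs dorsoventrally from the ventral origin),
#' mean reporter intensity, an optional nuclear-stain channel used for
#' dead-cell exclusion, an optional slice label, and an optional
#' progenitor-domain label (`"MN"`, `"IN"` or `"none"`). Excluded nuclei
#' are ignored by every downstream operation.
#'
#' @param df data frame with at least `nucleus_id`, `x_um`, `y_um`,
#'   `intensity`; optional `stain`, `slice`, `domain`, `excluded`.
#' @return A validated data frame of class `"nucleus_table"`.
#' @export
nucleus_table <- function(df) {
  need <- c("nucleus_id", "x_um", "y_um", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("nucleus table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("x_um", "y_um", "intensity")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("non-finite ", col, " at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  bad <- which(df$intensity < 0)
  if (length(bad)) {
    stop("negative intensity at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$nucleus_id)) stop("duplicate nucleus_id values", call. = FALSE)
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (is.null(df$domain)) df$domain <- "none"
  if (is.null(df$slice)) df$slice <- 1L
  class(df) <- c("nucleus_table", "data.frame")
  df
}

active_nuclei <- function(tab) tab[!tab$excluded, , drop = FALSE]

#' Read and write nucleus tables
#'
#' CSV with mandatory header `nucleus_id,x_um,y_um,intensity` and any of
#' the optional columns (`stain`, `slice`, `domain`, `excluded`); unknown
#' columns are preserved. Coordinates are micrometres.
#'
#' @param path CSV file path.
#' @param tab a `"nucleus_table"`.
#' @return `read_nucleus_table()` returns a validated
#'   [nucleus_table()]; `write_nucleus_table()` returns `path`
#'   invisibly.
#' @export
read_nucleus_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nucleus_table(df)
}

#' @rdname read_nucleus_table
#' @export
write_nucleus_table <- function(tab, path) {
  stopifnot(inherits(tab, "nucleus_table"))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag dead cells by outlying nuclear-stain intensity
#'
#' Dead cells take up disproportionate nuclear stain (membrane
#' permeability, condensed chromatin); the top fraction of nuclei by
#' stain intensity is flagged per slice. Exactly
#' `floor(top_frac * n)` nuclei are flagged in a slice of `n`; ties are
#' broken by nucleus id for reproducibility.
#'
#' @param tab a [nucleus_table()] with a `stain` column.
#' @param top_frac fraction flagged per slice (default 0.04).
#' @return The table with updated `excluded` flags.
#' @export
exclude_dead <- function(tab, top_frac = 0.04) {
  stopifnot(inherits(tab, "nucleus_table"))
  if (is.null(tab$stain)) stop("no nuclear-stain channel in table", call. = FALSE)
  if (top_frac < 0 || top_frac >= 1) stop("top_frac must be in [0, 1)", call. = FALSE)
  for (sl in unique(tab$slice)) {
    rows <- which(tab$slice == sl)
    k <- floor(top_frac * length(rows))
    if (k > 0) {
      ord <- rows[order(-tab$stain[rows], tab$nucleus_id[rows])]
      tab$excluded[ord[seq_len(k)]] <- TRUE
    }
  }
  tab
}

#' Quantile-normalise intensity sets across experiments
#'
#' Maps each set onto the common mean order-statistic distribution so
#' that intensities are comparable across experiments while within-set
#' ranks are preserved. Sets of unequal size are handled by linear
#' interpolation of the sorted values on a common quantile grid.
#'
#' @param sets list of numeric vectors (>= 2 non-empty sets).
#' @return List of normalised vectors, same shapes and order.
#' @export
#' @examples
#' quantile_normalize(list(c(1, 2, 3), c(10, 20, 30)))
quantile_normalize <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) stop("need >= 2 sets", call. = FALSE)
  if (any(vapply(sets, length, 1L) == 0)) stop("empty set", call. = FALSE)
  n_ref <- max(vapply(sets, length, 1L))
  grid <- (seq_len(n_ref) - 0.5) / n_ref
  sorted_on_grid <- vapply(sets, function(x) {
    sx <- sort(x)
    if (length(sx) == 1) return(rep(sx, n_ref))
    q <- (seq_along(sx) - 0.5) / length(sx)
    stats::approx(q, sx, grid, rule = 2)$y
  }, numeric(n_ref))
  ref <- rowMeans(sorted_on_grid)
  lapply(sets, function(x) {
    q <- (rank(x, ties.method = "average") - 0.5) / length(x)
    stats::approx(grid, ref, q, rule = 2)$y
  })
}

#' Geometric intensity bins
#'
#' Assigns each nucleus one of six intensity bins such that nuclei
#' within an 80-120% range of each other (a ratio of at most 1.5, the
#' amplitude of HES5 ultradian oscillations) share a bin. Bin edges
#' descend geometrically from the maximum value by factors of 1.5
#' (edges `max / 1.5^k`); bin 1 is the brightest, and values below the
#' lowest edge fall in bin 6.
#'
#' @param values positive intensities.
#' @return List with `bin` (integer 1-6 per value) and `bin_edges`
#'   (descending, length 7).
#' @export
bin_intensities <- function(values) {
  if (any(values <= 0)) stop("intensities must be > 0 to bin geometrically", call. = FALSE)
  edges <- max(values) / 1.5^(0:6)
  bin <- 7L - findInterval(values, rev(edges), left.open = TRUE, rightmost.closed = FALSE)
  bin[bin > 6L] <- 6L
  bin[bin < 1L] <- 1L
  list(bin = as.integer(bin), bin_edges = edges)
}

#' Detect microclusters of similar-intensity nuclei
#'
#' A microcluster is a group of two or more nuclei of the same intensity
#' bin whose centroids are mutually reachable through steps shorter than
#' `dmax` along which the connecting segment does not pass within one
#' nuclear radius of any different-bin nucleus (an interceding cell
#' blocks the path). Clusters are segmented separately for the top two
#' intensity bins. Dorsoventral and apical-basal diameters are reported
#' in cell units from the centroid span.
#'
#' @param tab a [nucleus_table()].
#' @param bin_levels intensity bins to segment (default `c(1, 2)`).
#' @param dmax linking distance, micrometres; default (`NULL`) is
#'   `dmax_factor` times the mean nearest-neighbour centroid distance.
#' @param dmax_factor multiplier for the automatic `dmax` (default 2.5).
#' @param r_nuc blocking radius around a different-bin nucleus,
#'   micrometres (default 4, about a nuclear radius).
#' @return An object of class `"microcluster_set"`: `clusters` data
#'   frame (`cluster_id`, `intensity_bin`, `n_cells`,
#'   `dv_diameter_cells`, `ab_diameter_cells`, `centroid_x_um`,
#'   `centroid_y_um`), `members` (list of nucleus-id vectors), `dmax_um`,
#'   `bin_edges`, `mean_nn_um`.
#' @export
detect_microclusters <- function(tab, bin_levels = c(1L, 2L), dmax = NULL,
                                 dmax_factor = 2.5, r_nuc = 4) {
  stopifnot(inherits(tab, "nucleus_table"))
  tab <- active_nuclei(tab)
  if (nrow(tab) < 2) stop("need at least 2 non-excluded nuclei", call. = FALSE)
  bins <- bin_intensities(tab$intensity)
  xy <- cbind(tab$x_um, tab$y_um)
  dmat <- as.matrix(stats::dist(xy))
  nn <- apply(dmat + diag(Inf, nrow(dmat)), 1, min)
  mean_nn <- mean(nn)
  if (is.null(dmax)) dmax <- dmax_factor * mean_nn

  clusters <- list(); members <- list(); cid <- 0L
  for (lev in bin_levels) {
    in_bin <- which(bins$bin == lev)
    if (length(in_bin) < 2) next
    blockers <- xy[bins$bin != lev, , drop = FALSE]
    n_b <- length(in_bin)
    parent <- seq_len(n_b)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (a in seq_len(n_b - 1)) for (b in (a + 1):n_b) {
      ia <- in_bin[a]; ib <- in_bin[b]
      if (dmat[ia, ib] >= dmax) next
      if (segment_blocked(xy[ia, ], xy[ib, ], blockers, r_nuc)) next
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
    comp <- vapply(seq_len(n_b), find, 1L)
    for (grp in split(in_bin, comp)) {
      if (length(grp) < 2) next
      cid <- cid + 1L
      span_cells <- function(v) floor(diff(range(v)) / mean_nn + 0.5) + 1L
      clusters[[cid]] <- data.frame(
        cluster_id = cid, intensity_bin = lev, n_cells = length(grp),
        dv_diameter_cells = span_cells(tab$y_um[grp]),
        ab_diameter_cells = span_cells(tab$x_um[grp]),
        centroid_x_um = mean(tab$x_um[grp]),
        centroid_y_um = mean(tab$y_um[grp])
      )
      members[[cid]] <- tab$nucleus_id[grp]
    }
  }
  structure(list(
    clusters = if (cid) do.call(rbind, clusters) else data.frame(
      cluster_id = integer(0), intensity_bin = integer(0), n_cells = integer(0),
      dv_diameter_cells = integer(0), ab_diameter_cells = integer(0),
      centroid_x_um = numeric(0), centroid_y_um = numeric(0)),
    members = members, dmax_um = dmax, bin_edges = bins$bin_edges,
    mean_nn_um = mean_nn
  ), class = "microcluster_set")
}

# does the a-b segment pass within r of any blocker point?
segment_blocked <- function(a, b, blockers, r) {
  if (nrow(blockers) == 0) return(FALSE)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(FALSE)
  t <- ((blockers[, 1] - a[1]) * ab[1] + (blockers[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- a[1] + t * ab[1] - blockers[, 1]
  dy <- a[2] + t * ab[2] - blockers[, 2]
  any(dx * dx + dy * dy < r * r)
}

#' @export
print.microcluster_set <- function(x, ...) {
  cat(sprintf("Microclusters: %d detected (dmax %.1f um, mean NN distance %.1f um)\n",
              nrow(x$clusters), x$dmax_um, x$mean_nn_um))
  if (nrow(x$clusters)) {
    cat(sprintf("  sizes: %s cells; bins: %s\n",
                paste(sort(unique(x$clusters$n_cells)), collapse = ","),
                paste(sort(unique(x$clusters$intensity_bin)), collapse = ",")))
  }
  invisible(x)
}

#' Successive dorsoventral distances between microclusters
#'
#' Sorts cluster centroids of each intensity bin by dorsoventral
#' position and returns the successive centre-to-centre distances, in
#' micrometres and in cell units (mean inter-nuclear distance).
#'
#' @param mcs a `"microcluster_set"` from [detect_microclusters()].
#' @param same_bin_only compute within each intensity bin separately
#'   (default TRUE).
#' @return Data frame with `intensity_bin`, `distance_um`,
#'   `distance_cells`; zero rows when fewer than two clusters share a
#'   bin.
#' @export
intercluster_distances <- function(mcs, same_bin_only = TRUE) {
  stopifnot(inherits(mcs, "microcluster_set"))
  cl <- mcs$clusters
  groups <- if (same_bin_only) split(cl, cl$intensity_bin) else list(cl)
  out <- lapply(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    y <- sort(g$centroid_y_um)
    data.frame(intensity_bin = g$intensity_bin[1], distance_um = diff(y))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(intensity_bin = integer(0), distance_um = numeric(0),
                      distance_cells = numeric(0)))
  }
  out$distance_cells <- out$distance_um / mcs$mean_nn_um
  rownames(out) <- NULL
  out
}

#' Randomisation controls for microcluster detection
#'
#' Generates control tables with the same nuclear geometry but scrambled
#' intensities: `Rnd1` shuffles the observed intensities between nuclei,
#' `Rnd2` samples fresh intensities from a normal distribution with the
#' observed mean and SD, truncated at zero. Real tissue shows
#' microclusters of several cells; randomised images produce mostly
#' doublets.
#'
#' @param tab a [nucleus_table()].
#' @param mode `"Rnd1"` or `"Rnd2"`.
#' @param reps replicates (default 20).
#' @param seed RNG seed.
#' @return List of `reps` nucleus tables.
#' @export
randomize_intensities <- function(tab, mode = c("Rnd1", "Rnd2"), reps = 20,
                                  seed = 1L) {
  stopifnot(inherits(tab, "nucleus_table"))
  mode <- match.arg(mode)
  set.seed(seed)
  act <- which(!tab$excluded)
  mu <- mean(tab$intensity[act]); sdv <- stats::sd(tab$intensity[act])
  lapply(seq_len(reps), function(i) {
    out <- tab
    if (mode == "Rnd1") {
      out$intensity[act] <- sample(tab$intensity[act])
    } else {
      v <- stats::rnorm(length(act), mu, sdv)
      while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, sdv)
      out$intensity[act] <- v
    }
    out
  })
}

#' Centre of intensity
#'
#' Intensity-weighted mean centroid of the non-excluded nuclei (centre
#' of mass with intensity as mass).
#'
#' @param tab a [nucleus_table()].
#' @return Named numeric `c(x_um, y_um)`.
#' @export
center_of_intensity <- function(tab) {
  stopifnot(inherits(tab, "nucleus_table"))
  tab <- active_nuclei(tab)
  if (nrow(tab) == 0) stop("no non-excluded nuclei", call. = FALSE)
  w <- tab$intensity
  if (sum(w) == 0) stop("all intensities zero: centre of intensity undefined", call. = FALSE)
  c(x_um = sum(w * tab$x_um) / sum(w), y_um = sum(w * tab$y_um) / sum(w))
}

#' Remove the radial intensity gradient
#'
#' Tissue images carry a radial gradient of HES5 intensity away from a
#' focal centre. Nuclei are sorted into `zones` equal-width radial zones
#' around the centre of intensity, a polynomial of degree 3 is fitted to
#' zone-mean intensity versus zone mid-radius, and the fitted zone value
#' is subtracted from every nucleus in the zone. Empty zones are merged
#' with their inner neighbour (with a warning).
#'
#' @param tab a [nucleus_table()].
#' @param zones number of radial zones (default 5).
#' @param poly_degree polynomial degree of the radial fit (default 3).
#' @return List of class `"gradient_model"` result: `table` (corrected
#'   intensities; may be negative after subtraction), `model` with
#'   `coi_x`, `coi_y`, `zone_edges_um`, `zone_mid_um`, `zone_mean`,
#'   `zone_fit`.
#' @export
remove_radial_gradient <- function(tab, zones = 5, poly_degree = 3) {
  stopifnot(inherits(tab, "nucleus_table"))
  act <- which(!tab$excluded)
  if (length(act) < 5 * zones) {
    stop("need at least ", 5 * zones, " nuclei for a ", zones, "-zone fit", call. = FALSE)
  }
  # robust centre for already-corrected (near-zero-mean) inputs
  w <- pmax(tab$intensity[act], 0)
  coi <- if (sum(w) > 0) {
    c(x_um = sum(w * tab$x_um[act]) / sum(w),
      y_um = sum(w * tab$y_um[act]) / sum(w))
  } else {
    c(x_um = mean(tab$x_um[act]), y_um = mean(tab$y_um[act]))
  }
  r <- sqrt((tab$x_um[act] - coi["x_um"])^2 + (tab$y_um[act] - coi["y_um"])^2)
  edges <- seq(0, max(r) * (1 + 1e-9), length.out = zones + 1)
  zone <- findInterval(r, edges, rightmost.closed = TRUE)
  zone[zone < 1] <- 1L
  counts <- tabulate(zone, zones)
  if (any(counts == 0)) {
    warning("empty radial zone(s) merged with inner neighbour")
    for (z in which(counts == 0)) zone[zone == z] <- max(1L, z - 1L)
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  used <- sort(unique(zone))
  zmean <- vapply(used, function(z) mean(tab$intensity[act][zone == z]), numeric(1))
  deg <- min(poly_degree, length(used) - 1)
  if (deg >= 1) {
    fit <- stats::lm(zmean ~ stats::poly(mids[used], deg, raw = TRUE))
    fitted_zone <- as.vector(stats::fitted(fit))
    coefs <- stats::coef(fit)
  } else {
    fitted_zone <- zmean
    coefs <- zmean
  }
  corr <- tab
  corr$intensity[act] <- tab$intensity[act] - fitted_zone[match(zone, used)]
  list(table = corr,
       model = list(coi_x = unname(coi["x_um"]), coi_y = unname(coi["y_um"]),
                    zone_edges_um = edges, zone_mid_um = mids[used],
                    zone_mean = zmean, zone_fit = fitted_zone,
                    coefficients = coefs))
}

#' Intensity correlation by neighbour rank and by distance
#'
#' For each neighbour rank k up to `max_rank`, the Pearson correlation
#' between each nucleus's intensity and that of its k-th nearest
#' neighbour. For distance, all nucleus pairs are binned by centroid
#' distance and the correlation of member intensities computed per bin,
#' with an order-2 polynomial fit of r versus distance.
#'
#' @param tab a [nucleus_table()].
#' @param max_rank largest neighbour rank (default 8).
#' @param bin_um distance bin width, micrometres (default 10, one cell).
#' @param max_distance_um largest pair distance analysed (default: half
#'   the spatial extent).
#' @return List with `by_rank` (data frame `rank`, `r`), `by_distance`
#'   (data frame `distance_um` bin centre, `r`, `n_pairs`) and
#'   `distance_fit` (order-2 polynomial coefficients of r vs distance).
#' @export
neighbor_correlations <- function(tab, max_rank = 8, bin_um = 10,
                                  max_distance_um = NULL) {
  stopifnot(inherits(tab, "nucleus_table"))
  tab <- active_nuclei(tab)
  n <- nrow(tab)
  if (n < max_rank + 1) stop("need at least max_rank + 1 nuclei", call. = FALSE)
  if (stats::sd(tab$intensity) == 0) {
    stop("constant intensities: correlation undefined", call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(cbind(tab$x_um, tab$y_um)))
  diag(dmat) <- Inf
  nn_order <- apply(dmat, 1, order)
  by_rank <- data.frame(
    rank = seq_len(max_rank),
    r = vapply(seq_len(max_rank), function(k) {
      stats::cor(tab$intensity, tab$intensity[nn_order[k, ]])
    }, numeric(1))
  )
  if (is.null(max_distance_um)) {
    max_distance_um <- max(dmat[is.finite(dmat)]) / 2
  }
  pairs <- which(upper.tri(dmat) & dmat <= max_distance_um, arr.ind = TRUE)
  d <- dmat[pairs]
  bin <- floor(d / bin_um)
  ub <- sort(unique(bin))
  by_distance <- do.call(rbind, lapply(ub, function(b) {
    sel <- bin == b
    if (sum(sel) < 3) return(NULL)
    # symmetrised pair correlation
    a <- c(tab$intensity[pairs[sel, 1]], tab$intensity[pairs[sel, 2]])
    bb <- c(tab$intensity[pairs[sel, 2]], tab$intensity[pairs[sel, 1]])
    data.frame(distance_um = (b + 0.5) * bin_um, r = stats::cor(a, bb),
               n_pairs = sum(sel))
  }))
  fit <- if (!is.null(by_distance) && nrow(by_distance) >= 3) {
    stats::coef(stats::lm(r ~ stats::poly(distance_um, 2, raw = TRUE),
                          data = by_distance))
  } else NULL
  list(by_rank = by_rank, by_distance = by_distance, distance_fit = fit)
}

#' Neighbour-pair concentration differences by domain
#'
#' Absolute HES5 concentration difference between every nucleus and its
#' nearest neighbour, normalised by the mean concentration of the
#' nucleus's progenitor domain. Alternating high-low patterns give large
#' normalised differences; smooth microcluster patterns give small ones.
#'
#' @param tab a [nucleus_table()] with informative `domain` labels.
#' @return Data frame with `nucleus_id`, `neighbor_id`, `domain`,
#'   `abs_diff`, `norm_diff`.
#' @export
neighbor_concentration_diff <- function(tab) {
  stopifnot(inherits(tab, "nucleus_table"))
  tab <- active_nuclei(tab)
  if (any(tab$domain == "none")) {
    stop("all nuclei need a domain label (MN/IN)", call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(cbind(tab$x_um, tab$y_um)))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, which.min)
  dom_mean <- tapply(tab$intensity, tab$domain, mean)
  ad <- abs(tab$intensity - tab$intensity[nn])
  data.frame(
    nucleus_id = tab$nucleus_id, neighbor_id = tab$nucleus_id[nn],
    domain = tab$domain, abs_diff = ad,
    norm_diff = ad / as.numeric(dom_mean[tab$domain])
  )
}
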