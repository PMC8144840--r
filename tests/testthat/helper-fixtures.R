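# Shared builders and independent oracles used across test files.

quick_sim <- function(p0 = Inf, n_rows = 4, n_cols = 6, t_end = 1800,
                      burn_in = 300, seed = 1, noise = TRUE, ...) {
  scp <- single_cell_params(noise_enabled = noise)
  simulate_hes5(scp, coupling_params(p0, ...),
                hex_lattice(n_rows, n_cols),
                sim_config(t_end = t_end, burn_in = burn_in, seed = seed))
}

# fake minimal hes_sim carrying a prescribed protein matrix
fake_sim <- function(protein, record_every = 15) {
  lat <- hex_lattice(2, max(2, ceiling(nrow(protein) / 2)))
  structure(list(times = (seq_len(ncol(protein)) - 1) * record_every,
                 protein = protein, mrna = protein * 0,
                 lattice = lat, scp = single_cell_params(),
                 cp = coupling_params(Inf),
                 config = sim_config(t_end = ncol(protein) * record_every,
                                     burn_in = 0,
                                     record_every = record_every),
                 seed = 1L),
            class = "hes_sim")
}

# Independent neighbour oracle: two lattice cells are neighbours iff their
# centroid distance is one pitch (torus metric under periodic boundary).
oracle_neighbors <- function(lat) {
  n <- lat$n_cells
  out <- vector("list", n)
  Lx <- lat$n_rows * lat$cell_pitch_um * sqrt(3) / 2
  Ly <- lat$n_cols * lat$cell_pitch_um
  for (i in seq_len(n)) {
    dx <- abs(lat$x_um - lat$x_um[i])
    dy <- abs(lat$y_um - lat$y_um[i])
    if (lat$boundary == "periodic") {
      dx <- pmin(dx, Lx - dx)
      dy <- pmin(dy, Ly - dy)
    }
    d <- sqrt(dx^2 + dy^2)
    out[[i]] <- sort(setdiff(which(d < lat$cell_pitch_um * 1.01), i))
  }
  out
}

# Brute-force microcluster oracle: explicit all-pairs adjacency (distance +
# segment blocking re-implemented independently) and reachability through
# repeated boolean matrix squaring.
oracle_microclusters <- function(tab, bin_levels = c(1L, 2L), dmax, r_nuc = 4) {
  tab <- tab[!tab$excluded, , drop = FALSE]
  bins <- bin_intensities(tab$intensity)$bin
  n <- nrow(tab)
  out <- list()
  for (lev in bin_levels) {
    idx <- which(bins == lev)
    if (length(idx) < 2) next
    m <- length(idx)
    adj <- diag(TRUE, m)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a >= b) next
      pa <- c(tab$x_um[idx[a]], tab$y_um[idx[a]])
      pb <- c(tab$x_um[idx[b]], tab$y_um[idx[b]])
      if (sqrt(sum((pa - pb)^2)) >= dmax) next
      blocked <- FALSE
      for (k in which(bins != lev)) {
        pk <- c(tab$x_um[k], tab$y_um[k])
        # distance from point to segment by direct minimisation over a grid
        tt <- seq(0, 1, length.out = 201)
        px <- pa[1] + tt * (pb[1] - pa[1]); py <- pa[2] + tt * (pb[2] - pa[2])
        if (min(sqrt((px - pk[1])^2 + (py - pk[2])^2)) < r_nuc) {
          blocked <- TRUE; break
        }
      }
      if (!blocked) adj[a, b] <- adj[b, a] <- TRUE
    }
    reach <- adj
    for (s in seq_len(ceiling(log2(max(m, 2))))) {
      reach <- (reach %*% reach) > 0
    }
    comp <- unique(apply(reach, 1, function(r) paste(which(r), collapse = ",")))
    for (cstr in comp) {
      mem <- idx[as.integer(strsplit(cstr, ",")[[1]])]
      if (length(mem) >= 2) {
        out[[length(out) + 1L]] <- sort(tab$nucleus_id[mem])
      }
    }
  }
  out
}

# canonical form of cluster memberships for set comparison
membership_key <- function(member_list) {
  sort(vapply(member_list, function(m) paste(sort(m), collapse = "-"), ""))
}

# Tissue-like nucleus field: jittered hexagonal packing, right-skewed
# (lognormal) intensity spread over several geometric bins, five planted
# five-cell bright clusters near the 97th percentile.
lognormal_field <- function(seed = 7, sdlog = 0.6) {
  set.seed(seed)
  n_r <- 10; n_c <- 25; n <- n_r * n_c
  rows <- rep(1:n_r, times = n_c); cols <- rep(1:n_c, each = n_r)
  y <- (cols - 1 + 0.5 * (rows %% 2)) * 10 + rnorm(n, 0, 1)
  x <- (rows - 1) * 10 * sqrt(3) / 2 + rnorm(n, 0, 1)
  I <- 100 * exp(rnorm(n, 0, sdlog))
  for (k in 0:4) {
    sel <- which(cols %in% (1 + k * 5):(2 + k * 5) & rows %in% 5:7)[1:5]
    I[sel] <- quantile(I, 0.97) * exp(rnorm(5, 0, 0.1))
  }
  nucleus_table(data.frame(nucleus_id = seq_len(n), x_um = x, y_um = y,
                           intensity = I))
}
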