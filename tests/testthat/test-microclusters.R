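make_table <- function(x, y, I, stain = NULL, slice = NULL) {
  df <- data.frame(nucleus_id = seq_along(x), x_um = x, y_um = y, intensity = I)
  if (!is.null(stain)) df$stain <- stain
  if (!is.null(slice)) df$slice <- slice
  nucleus_table(df)
}

test_that("nucleus tables validate their schema with row numbers", {
  expect_s3_class(make_table(1:3, 1:3, c(10, 20, 30)), "nucleus_table")
  expect_error(nucleus_table(data.frame(nucleus_id = 1, y_um = 1, intensity = 1)),
               "x_um")
  expect_error(make_table(1:3, 1:3, c(10, -2, 30)), "row\\(s\\) 2")
  expect_error(make_table(c(1, NA, 3), 1:3, c(1, 2, 3)), "non-finite x_um")
})

test_that("nucleus tables round-trip through CSV exactly", {
  tab <- make_table(c(1.25, 2.5, 10.125), c(0, 5.5, 9.75), c(10, 20, 30),
                    stain = c(1, 2, 3))
  tab$domain <- c("MN", "IN", "MN")
  path <- tempfile(fileext = ".csv")
  write_nucleus_table(tab, path)
  back <- read_nucleus_table(path)
  expect_equal(back$x_um, tab$x_um)
  expect_equal(back$intensity, tab$intensity)
  expect_equal(back$domain, tab$domain)
})

test_that("dead-cell exclusion flags the top stain fraction per slice", {
  set.seed(1)
  tab <- make_table(runif(100), runif(100), runif(100, 50, 100),
                    stain = runif(100))
  out <- exclude_dead(tab)
  expect_equal(sum(out$excluded), 4)
  expect_true(all(tab$stain[out$excluded] >= sort(tab$stain, decreasing = TRUE)[4]))
  # ties break by nucleus id, deterministically
  tie <- make_table(1:50, 1:50, rep(1, 50), stain = rep(7, 50))
  out2 <- exclude_dead(tie)
  expect_equal(which(out2$excluded), 1:2)
  expect_equal(sum(exclude_dead(tie, top_frac = 0)$excluded), 0)
  expect_error(exclude_dead(make_table(1:5, 1:5, 1:5)), "stain")
})

test_that("quantile normalisation maps sets onto mean order statistics", {
  got <- quantile_normalize(list(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(got[[1]], c(5.5, 11, 16.5))
  expect_equal(got[[2]], c(5.5, 11, 16.5))
  # identical sets are unchanged
  same <- quantile_normalize(list(c(4, 8, 15), c(4, 8, 15)))
  expect_equal(same[[1]], c(4, 8, 15))
  # ranks preserved within each set; distributions identical across sets
  set.seed(3)
  sets <- list(rlnorm(40, 5), rlnorm(40, 6), rlnorm(40, 5.5))
  qn <- quantile_normalize(sets)
  for (i in 1:3) expect_equal(cor(sets[[i]], qn[[i]], method = "spearman"), 1)
  expect_equal(sort(qn[[1]]), sort(qn[[2]]))
  expect_error(quantile_normalize(list(1:3)), ">= 2 sets")
  expect_error(quantile_normalize(list(1:3, numeric(0))), "empty")
})

test_that("quantile normalisation agrees with limma on equal-length sets", {
  set.seed(4)
  m <- cbind(rgamma(60, 2, 0.1), rgamma(60, 5, 0.05))
  ours <- quantile_normalize(list(m[, 1], m[, 2]))
  ref <- limma::normalizeQuantiles(m)
  expect_equal(ours[[1]], ref[, 1], tolerance = 1e-8)
  expect_equal(ours[[2]], ref[, 2], tolerance = 1e-8)
})

test_that("geometric intensity bins implement the 80-120% same-bin rule", {
  b <- bin_intensities(c(100, 90))
  expect_equal(b$bin[1], b$bin[2])
  expect_false(bin_intensities(c(100, 60))$bin[1] ==
                 bin_intensities(c(100, 60))$bin[2])
  e <- bin_intensities(c(1500, 800, 100))$bin_edges
  expect_equal(e[2], 1000)
  expect_equal(e[3], 1500 / 2.25, tolerance = 1e-9)
  # values below the lowest edge collapse into bin 6
  expect_equal(bin_intensities(c(1500, 0.001))$bin[2], 6L)
  expect_error(bin_intensities(c(5, 0)), "> 0")
})

test_that("microcluster detection honours distance and interceding-cell rules", {
  # two bright nuclei 8 um apart link into one cluster
  tab <- make_table(c(0, 8, 100, 108, 104), c(0, 0, 0, 0, 50),
                    c(200, 210, 205, 195, 60))
  mcs <- detect_microclusters(tab, dmax = 23)
  expect_equal(nrow(mcs$clusters), 2)
  expect_true(all(mcs$clusters$n_cells == 2))
  # a dim nucleus centred on the connecting segment blocks the link
  blocked <- make_table(c(0, 8, 4), c(0, 0, 0.5), c(200, 210, 60))
  expect_equal(nrow(detect_microclusters(blocked, dmax = 23)$clusters), 0)
  # moving the interceder far off the segment restores the cluster
  clear <- make_table(c(0, 8, 4), c(0, 0, 30), c(200, 210, 60))
  expect_equal(nrow(detect_microclusters(clear, dmax = 23)$clusters), 1)
})

test_that("detection matches the brute-force oracle on random planted fields", {
  set.seed(99)
  for (rep in 1:14) {
    sf <- synth_nucleus_field(n_cells = 60 + 10 * (rep %% 4),
                              cluster_size = 2 + rep %% 4,
                              period_um = 40, jitter_um = 1,
                              noise_sd = 8, seed = rep)
    mcs <- detect_microclusters(sf$table, dmax = 24)
    orc <- oracle_microclusters(sf$table, dmax = 24)
    expect_identical(membership_key(mcs$members), membership_key(orc),
                     info = paste("field", rep))
  }
})

test_that("planted clusters are recovered exactly with clean intensities", {
  sf <- synth_nucleus_field(n_cells = 300, cluster_size = 4, period_um = 40,
                            noise_sd = 0, alpha = 0, seed = 9)
  mcs <- detect_microclusters(sf$table, bin_levels = 1L)
  expect_identical(membership_key(mcs$members),
                   membership_key(sf$truth$planted_cluster_members))
  expect_true(all(mcs$clusters$n_cells == 4))
})

test_that("detection is invariant to rigid motion and intensity scaling", {
  sf <- synth_nucleus_field(n_cells = 120, cluster_size = 3, noise_sd = 5,
                            seed = 31)
  base <- detect_microclusters(sf$table, dmax = 24)
  th <- 0.6
  rot <- sf$table
  x <- rot$x_um; y <- rot$y_um
  rot$x_um <- 12 + cos(th) * x - sin(th) * y
  rot$y_um <- -5 + sin(th) * x + cos(th) * y
  rot$intensity <- rot$intensity * 3.7
  moved <- detect_microclusters(rot, dmax = 24)
  expect_identical(membership_key(moved$members), membership_key(base$members))
})

test_that("intercluster distances read out the planted spatial period", {
  mcs <- list(clusters = data.frame(cluster_id = 1:3, intensity_bin = 1,
                                    n_cells = 3, dv_diameter_cells = 2,
                                    ab_diameter_cells = 2,
                                    centroid_x_um = 0,
                                    centroid_y_um = c(10, 50, 90)),
              members = list(), dmax_um = 20, mean_nn_um = 10)
  class(mcs) <- "microcluster_set"
  expect_equal(intercluster_distances(mcs)$distance_um, c(40, 40))
  mcs$clusters <- mcs$clusters[1, ]
  expect_equal(nrow(intercluster_distances(mcs)), 0)
  # planted field: successive same-bin cluster centroids ~40 um = 4 cells
  sf <- synth_nucleus_field(n_cells = 400, cluster_size = 4, period_um = 40,
                            noise_sd = 0, seed = 17)
  icd <- intercluster_distances(detect_microclusters(sf$table, bin_levels = 1L))
  expect_equal(median(icd$distance_um), 40, tolerance = 0.08)
  expect_equal(median(icd$distance_cells), 4, tolerance = 0.4)
})

test_that("randomisation controls keep geometry and moments but break clusters", {
  sf <- synth_nucleus_field(n_cells = 250, cluster_size = 5, noise_sd = 10,
                            seed = 23)
  r1 <- randomize_intensities(sf$table, "Rnd1", reps = 5, seed = 2)
  for (t1 in r1) {
    expect_equal(sort(t1$intensity), sort(sf$table$intensity))
    expect_equal(t1$x_um, sf$table$x_um)
  }
  r2 <- randomize_intensities(sf$table, "Rnd2", reps = 20, seed = 2)
  mu <- mean(sf$table$intensity); sdv <- sd(sf$table$intensity)
  for (t2 in r2[1:5]) {
    expect_true(all(t2$intensity > 0))
    expect_lt(abs(mean(t2$intensity) - mu), 3.5 * sdv / sqrt(nrow(t2)))
  }
  pooled <- unlist(lapply(r2, `[[`, "intensity"))
  expect_lt(abs(sd(pooled) - sdv), 0.05 * sdv)

  # randomised images carry smaller clusters than the planted image
  # (tissue-like field: jittered packing, lognormal intensity spread,
  # blocking radius at the packing covering radius pitch/sqrt(3))
  tab <- lognormal_field()
  r_cov <- 10 / sqrt(3)
  planted_sizes <- detect_microclusters(tab, r_nuc = r_cov)$clusters$n_cells
  rnd_sizes <- unlist(lapply(
    c(randomize_intensities(tab, "Rnd1", 10, seed = 1),
      randomize_intensities(tab, "Rnd2", 10, seed = 2)),
    function(t) detect_microclusters(t, r_nuc = r_cov)$clusters$n_cells))
  expect_gt(mean(rnd_sizes <= 2), 0.5)    # doublets are the norm
  expect_gt(mean(planted_sizes), mean(rnd_sizes))
  expect_lt(max(rnd_sizes), nrow(tab) / 10)  # no percolating artefacts
})

test_that("centre of intensity is the intensity-weighted centroid", {
  sym <- make_table(c(0, 0, 10, 10), c(0, 10, 0, 10), rep(5, 4))
  expect_equal(unname(center_of_intensity(sym)), c(5, 5))
  hand <- make_table(c(0, 0, 10, 10), c(0, 10, 0, 10), c(1, 1, 1, 5))
  expect_equal(unname(center_of_intensity(hand)),
               c((10 + 50) / 8, (10 + 50) / 8))
  dom <- make_table(c(0, 100), c(0, 40), c(1e-6, 1000))
  expect_lt(abs(center_of_intensity(dom)["x_um"] - 100), 0.01)
  expect_error(center_of_intensity(make_table(1:3, 1:3, rep(0, 3))), "zero")
})

test_that("radial gradient removal flattens a planted I = Z + alpha*r field", {
  set.seed(6)
  sf <- synth_nucleus_field(n_cells = 300, cluster_size = 0, noise_sd = 10,
                            baseline = 200, alpha = 3, seed = 6)
  tab <- sf$table
  coi <- center_of_intensity(tab)
  r <- sqrt((tab$x_um - coi[1])^2 + (tab$y_um - coi[2])^2)
  expect_gt(cor(tab$intensity, r), 0.8)          # gradient dominates
  fixed <- remove_radial_gradient(tab)
  r2 <- sqrt((fixed$table$x_um - fixed$model$coi_x)^2 +
               (fixed$table$y_um - fixed$model$coi_y)^2)
  expect_lt(abs(cor(fixed$table$intensity, r2)), 0.25)
  # zone means of the corrected field are near zero
  zone <- findInterval(r2, fixed$model$zone_edges_um, rightmost.closed = TRUE)
  zmeans <- tapply(fixed$table$intensity, pmax(zone, 1), mean)
  expect_lt(max(abs(zmeans)), 0.15 * mean(tab$intensity))
  # idempotent within fit tolerance
  again <- remove_radial_gradient(fixed$table)
  expect_lt(mean(abs(again$table$intensity - fixed$table$intensity)),
            0.05 * sd(tab$intensity))
})

test_that("clusters survive gradient removal in a joint synthetic field", {
  sf <- synth_nucleus_field(n_cells = 300, cluster_size = 4, period_um = 40,
                            cluster_amp = 150, noise_sd = 5, alpha = 1.5,
                            seed = 13)
  fixed <- remove_radial_gradient(sf$table)$table
  fixed$intensity <- fixed$intensity - min(fixed$intensity) + 1
  mcs <- detect_microclusters(fixed)
  expect_gte(sum(mcs$clusters$n_cells >= 3), 3)
})

test_that("neighbour-rank correlations decay and vanish under randomisation", {
  sf <- synth_nucleus_field(n_cells = 300, cluster_size = 6, period_um = 40,
                            cluster_amp = 120, noise_sd = 1, seed = 41)
  nc <- neighbor_correlations(sf$table)
  expect_gt(nc$by_rank$r[1], 0.3)
  expect_gt(nc$by_rank$r[1], nc$by_rank$r[8])
  rnd <- randomize_intensities(sf$table, "Rnd1", reps = 1, seed = 5)[[1]]
  nr <- neighbor_correlations(rnd)
  expect_lt(max(abs(nr$by_rank$r)), 0.15)
  expect_error(neighbor_correlations(make_table(1:20, 1:20, rep(3, 20))),
               "constant")
})

test_that("distance correlations turn negative near the anti-phase distance", {
  # planted cosine intensity field with 40-um period along D-V
  set.seed(2)
  n_r <- 10; n_c <- 40
  rows <- rep(1:n_r, times = n_c); cols <- rep(1:n_c, each = n_r)
  y <- (cols - 1 + 0.5 * (rows %% 2)) * 10
  x <- (rows - 1) * 10 * sqrt(3) / 2
  I <- 200 + 80 * cos(2 * pi * y / 40) + rnorm(length(y), 0, 5)
  tab <- nucleus_table(data.frame(nucleus_id = seq_along(y), x_um = x,
                                  y_um = y, intensity = pmax(I, 1)))
  nc <- neighbor_correlations(tab, bin_um = 10, max_distance_um = 60)
  r_short <- nc$by_distance$r[nc$by_distance$distance_um == 5]
  r_anti <- nc$by_distance$r[nc$by_distance$distance_um == 25]
  expect_gt(r_short, 0.3)
  expect_lt(r_anti, -0.2)
})

test_that("neighbour concentration differences separate pattern types", {
  grid <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
  alternating <- 100 + 50 * (-1)^(round(grid$x / 10) + round(grid$y / 10))
  smooth <- 100 + 50 * sin(2 * pi * grid$y / 80)
  mk <- function(I) {
    t <- nucleus_table(data.frame(nucleus_id = seq_len(nrow(grid)),
                                  x_um = grid$x, y_um = grid$y, intensity = I))
    t$domain <- ifelse(grid$y < 50, "MN", "IN")
    t
  }
  expect_equal(neighbor_concentration_diff(mk(rep(80, nrow(grid))))$norm_diff,
               rep(0, nrow(grid)))
  d_alt <- neighbor_concentration_diff(mk(alternating))
  d_smooth <- neighbor_concentration_diff(mk(smooth))
  expect_gt(mean(d_alt$norm_diff), 2 * mean(d_smooth$norm_diff))
  # scale invariance of the normalised difference
  d_scaled <- neighbor_concentration_diff(mk(2 * alternating))
  expect_equal(d_scaled$norm_diff, d_alt$norm_diff)
  bad <- mk(alternating); bad$domain[3] <- "none"
  expect_error(neighbor_concentration_diff(bad), "domain")
})
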