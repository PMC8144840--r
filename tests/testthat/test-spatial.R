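test_that("spatial detrending removes polynomial trends and keeps the signal", {
  pos <- seq(0, 248, by = 2)
  poly4 <- 200 + 3 * pos - 0.05 * pos^2 + 2e-4 * pos^3 - 4e-7 * pos^4
  sp <- detrend_spatial(poly4, pos)
  expect_lt(max(abs(sp$detrended)), 1e-6 * max(abs(poly4)))
  wave <- 40 * cos(2 * pi * pos / 20)  # 12+ cycles: little leakage into the trend
  sp2 <- detrend_spatial(poly4 + wave, pos)
  expect_lt(sqrt(mean((sp2$detrended - wave)^2)), 0.05 * 40)
  expect_equal(detrend_spatial(rep(7, 60))$detrended, rep(0, 60))
  expect_error(detrend_spatial(1:10, poly_order = 4), "short")
  expect_error(detrend_spatial(1:100, poly_order = 3), "order")
})

test_that("bootstrap autocorrelation recovers planted periods within one bin", {
  pos <- seq(0, 248, by = 2)
  for (lam in c(20, 30, 40, 60)) {
    raw <- 500 + 2 * pos - 0.008 * pos^2 + 50 * cos(2 * pi * pos / lam)
    acr <- spatial_autocorr(detrend_spatial(raw, pos), n_boot = 100, seed = 7)
    expect_true(acr$is_periodic, info = paste("lambda", lam))
    expect_lte(abs(acr$peak_to_peak_mean_um - lam), 2, # one 2-um bin
               expected.label = lam)
  }
})

test_that("shuffling destroys detected periodicity", {
  pos <- seq(0, 198, by = 2)
  raw <- 50 * cos(2 * pi * pos / 40)
  set.seed(2)
  acr <- spatial_autocorr(sample(raw), um_per_bin = 2, n_boot = 100, seed = 3)
  expect_false(acr$is_periodic)
})

test_that("the periodicity call keeps its false-positive rate near nominal", {
  set.seed(11)
  hits <- replicate(100, {
    x <- rnorm(100)
    spatial_autocorr(x, um_per_bin = 2, n_boot = 60,
                     seed = sample.int(1e6, 1))$is_periodic
  })
  expect_lte(mean(hits), 0.07)  # ~5% nominal with binomial slack
})

test_that("Lomb-Scargle finds planted spatial frequencies", {
  pos <- seq(0, 248, by = 2)
  sp <- detrend_spatial(300 + 50 * cos(2 * pi * pos / 40), pos)
  ls <- lomb_scargle_period(sp)
  expect_lt(abs(ls$period_um - 40), 2)
  # two planted frequencies: both reported, mean of top two
  two <- 40 * cos(2 * pi * pos / 40) + 40 * cos(2 * pi * pos / 20)
  ls2 <- lomb_scargle_period(detrend_spatial(300 + two, pos))
  expect_gte(length(ls2$significant_periods_um), 2)
  expect_lt(abs(ls2$period_um - 30), 2)
  # white noise rarely clears P = 1e-4
  set.seed(4)
  nsig <- replicate(20, {
    length(lomb_scargle_period(rnorm(100), um_per_bin = 2)$significant_periods_um)
  })
  expect_lte(mean(nsig > 0), 0.1)
})

test_that("periodogram and ACF are invariant to offset and positive scaling", {
  pos <- seq(0, 198, by = 2)
  d <- 30 * cos(2 * pi * pos / 40) + rnorm(100, 0, 3)
  a1 <- spatial_autocorr(d, um_per_bin = 2, seed = 1)
  a2 <- spatial_autocorr(5 + 3 * d, um_per_bin = 2, seed = 1)
  expect_equal(a1$acf, a2$acf, tolerance = 1e-6)
  l1 <- lomb_scargle_period(d, um_per_bin = 2)
  l2 <- lomb_scargle_period(5 + 3 * d, um_per_bin = 2)
  expect_equal(l1$power, l2$power, tolerance = 1e-6)
})

test_that("peak-trough fold changes recover the planted amplitude ratio", {
  pos <- seq(0, 198, by = 2)
  prof <- detrend_spatial(100 + 50 * cos(2 * pi * pos / 40), pos)
  fc <- peak_trough_fold_change(prof)
  expect_gt(length(fc$fold_changes), 1)
  expect_equal(mean(fc$fold_changes), 3, tolerance = 0.15)
  flat <- detrend_spatial(rep(100, 100), pos)
  expect_length(peak_trough_fold_change(flat)$fold_changes, 0)
})

test_that("band persistence recovers a deterministic square-wave switcher", {
  # 14-h switching: exactly 7 h high / 7 h low per cycle
  tms <- seq(0, 56 * 60 - 15, by = 15)
  pos <- seq(0, 198, by = 2)
  state <- ifelse((tms / 60) %% 14 < 7, 1, -1)
  mat <- outer(sin(2 * pi * pos / 40), state) * 50 + 200
  bp <- band_persistence(kymograph(mat, 2, 15))
  expect_equal(median(bp$high_h), 7, tolerance = 0.05)
  expect_equal(median(bp$low_h), 7, tolerance = 0.05)
  expect_true(all(abs(bp$persistence_ratio - 1) < 0.1, na.rm = TRUE))
})

test_that("telegraph switching is recovered against a dwell-statistics oracle", {
  sk <- synth_kymograph(duration_h = 72, switch_persistence_h = 7,
                        noise_sd = 4, seed = 21)
  bp <- band_persistence(sk$kymo)
  got <- mean(c(bp$high_h, bp$low_h))
  # oracle: simulate the same per-frame telegraph, apply the same
  # censor-first/last-and-average readout to the true dwell intervals
  set.seed(77)
  oracle <- mean(replicate(400, {
    flips <- runif(72 * 4) < (0.25 / 7)
    r <- rle(cumsum(flips) %% 2)
    d <- r$lengths / 4
    if (length(d) > 2) mean(d[-c(1, length(d))]) else NA_real_
  }), na.rm = TRUE)
  expect_lt(abs(got - oracle) / oracle, 0.15)
})

test_that("constant bands yield undefined persistence ratios, not errors", {
  mat <- matrix(100, 20, 40)
  mat[1:10, ] <- mat[1:10, ] + sin(seq_len(40))  # only ventral band varies
  bp <- band_persistence(kymograph(mat, 2, 30), blur_um = 0)
  expect_true(any(is.na(bp$persistence_ratio)))
})

test_that("band clustering matches a brute-force average-linkage oracle", {
  set.seed(8)
  m <- matrix(rnorm(6 * 40), 6)
  cb <- cluster_bands(m)
  # O(n^3) reference: repeated merging of the closest pair with
  # average-linkage distance updates over the full distance matrix
  d <- as.matrix(dist(m))
  groups <- as.list(seq_len(6))
  heights <- c()
  while (length(groups) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  expect_equal(sort(cb$hclust$height), sort(heights), tolerance = 1e-9)

  # two identical bands merge first at distance zero
  m2 <- rbind(m[1, ], m[1, ], m[3:6, ])
  cb2 <- cluster_bands(m2)
  expect_equal(cb2$hclust$height[1], 0)
  expect_setequal(-cb2$hclust$merge[1, ], c(1, 2))

  # an anti-phase band joins two correlated switchers last
  t <- seq_len(60)
  trio <- rbind(sin(t / 4), sin(t / 4) + rnorm(60, 0, 0.1), -sin(t / 4))
  cb3 <- cluster_bands(trio)
  expect_setequal(-cb3$hclust$merge[1, ], c(1, 2))
})

test_that("phase maps track static and travelling planted patterns", {
  pos <- seq(0, 198, by = 2)
  tms <- seq(0, 12 * 60 - 15, by = 15)
  static <- outer(50 * cos(2 * pi * pos / 40), rep(1, length(tms))) + 200
  pm <- phase_map(kymograph(static, 2, 15), check_periodicity = FALSE)
  expect_true(all(pm$valid))
  for (b in 2:ncol(pm$phase)) expect_equal(pm$phase[, b], pm$phase[, 1])
  # wave advancing pi per 2-h block
  block_phase <- pi * floor(tms / 120)
  trav <- 200 + 50 * cos(outer(2 * pi * pos / 40, -block_phase, "+"))
  pmt <- phase_map(kymograph(trav, 2, 15), check_periodicity = FALSE)
  mid <- 30:70
  shift <- (pmt$phase[mid, 2] - pmt$phase[mid, 1]) %% (2 * pi)
  expect_lt(max(abs(shift - pi)), 0.2)
  # degenerate (flat) block flagged invalid
  static[, 1:8] <- 100
  pmd <- phase_map(kymograph(static, 2, 15), check_periodicity = FALSE)
  expect_false(pmd$valid[1])
  expect_true(all(is.na(pmd$phase[, 1])))
})

test_that("anterior-posterior correlation decays with planted correlation length", {
  expect_error(ap_correlation(matrix(1, 4, 2), 1), "one A-P position")
  set.seed(12)
  base <- 50 * cos(2 * pi * seq(0, 198, 2) / 40)
  prof <- function(z) base * exp(-z / 30) +
    sqrt(1 - exp(-2 * z / 30)) * 50 * rnorm(100) / sqrt(2)
  profs <- cbind(base, prof(10), prof(40), -base)
  res <- ap_correlation(profs, c(0, 10, 40, 80))
  expect_equal(ap_correlation(cbind(base, base), c(0, 0))$r, 1)
  expect_equal(res$r[res$i == 1 & res$j == 4], -1, tolerance = 1e-9)
  r_near <- res$r[res$i == 1 & res$j == 2]
  r_far <- res$r[res$i == 1 & res$j == 3]
  expect_gt(r_near, 0.5)
  expect_lt(r_far, r_near)
})

test_that("time-series detrending separates trend from oscillation", {
  tms <- seq(0, 24 * 60, by = 15)
  ramp <- 0.5 * tms
  osc <- 300 * sin(2 * pi * tms / 200)
  dt <- detrend_timeseries(ramp + osc, tms)
  expect_gt(cor(dt$detrended, osc), 0.98)
  expect_gt(cor(dt$trend, ramp), 0.98)
  pure <- detrend_timeseries(ramp, tms, zscore = FALSE)
  expect_lt(max(abs(pure$detrended)) / max(ramp), 0.02)
  # z-scored output is variance-normalised
  set.seed(5)
  wn <- detrend_timeseries(rnorm(200), zscore = TRUE)
  expect_equal(sd(wn$detrended), 1, tolerance = 0.1)
})

test_that("the MN/IN split sits 35 um ventral of the trend peak", {
  pos <- seq(0, 240, by = 2)
  bell <- 500 * exp(-(pos - 100)^2 / 4000)
  sp <- detrend_spatial(bell + 20 * cos(2 * pi * pos / 40), pos)
  sm <- split_mn_in(sp)
  expect_equal(sm$boundary_um, 100 - 35, tolerance = 6)
  expect_true(all(pos[sm$mn] < sm$boundary_um))
  # monotone trend: no split
  mono <- detrend_spatial(2 * pos + 10, pos)
  expect_warning(res <- split_mn_in(mono), "edge")
  expect_null(res)
})

test_that("per-segment periods are recovered after an MN/IN split", {
  pos <- seq(0, 298, by = 2)
  bell <- 800 * exp(-(pos - 160)^2 / 2 / 60^2)
  raw <- bell + ifelse(pos < 125, 40 * cos(2 * pi * pos / 20),
                       40 * cos(2 * pi * pos / 40))
  sp <- detrend_spatial(raw, pos)
  sm <- split_mn_in(sp)
  expect_equal(sm$boundary_um, 125, tolerance = 8)
  per_seg <- function(idx) {
    spatial_autocorr(detrend_spatial(raw[idx], pos[idx]),
                     n_boot = 60, seed = 2)$peak_to_peak_mean_um
  }
  expect_lt(abs(per_seg(sm$mn) - 20), 2.1)
  expect_lt(abs(per_seg(sm$in_) - 40), 2.1)
})
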