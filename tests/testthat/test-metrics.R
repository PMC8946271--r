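test_that("volume fractions count thresholds with the >= convention", {
  v <- array(c(1, 2, 3, 4), c(4, 1, 1))
  mask <- array(TRUE, c(4, 1, 1))
  expect_equal(volume_fraction_at(v, mask, 2.5), 50)
  expect_equal(volume_fraction_at(v, mask, 0), 100)
  u <- array(5, c(3, 1, 1))
  expect_equal(volume_fraction_at(u, array(TRUE, c(3, 1, 1)), 5), 100)
  expect_error(volume_fraction_at(v, mask & FALSE, 1), "empty mask")
})

test_that("hot-volume dose matches the descending-sort rule", {
  vals <- array(c(20, 18, 16, 14, 12, 10), c(6, 1, 1))
  mask <- array(TRUE, c(6, 1, 1))
  expect_equal(dose_at_volume_cc(vals, mask, 0.1, 0.05), 18)   # 2 voxels
  expect_equal(dose_at_volume_cc(vals, mask, 0.05, 0.05), 20)  # max dose
  expect_equal(dose_at_volume_cc(vals, mask, 0.075, 0.05), 19) # interpolated
  u <- array(7, c(5, 1, 1))
  expect_equal(dose_at_volume_cc(u, array(TRUE, c(5, 1, 1)), 0.12, 0.05), 7)
  expect_error(dose_at_volume_cc(vals, mask, 1, 0.05), "exceeds organ volume")

  # random case against an independent order-statistic oracle
  set.seed(4)
  x <- array(rnorm(400), c(20, 20, 1))
  mask2 <- array(runif(400) < 0.6, c(20, 20, 1))
  srt <- sort(x[mask2], decreasing = TRUE)
  for (k in c(1, 3, 10, 50))
    expect_equal(dose_at_volume_cc(x, mask2, k * 0.01, 0.01), srt[k])
})

test_that("temperature percentiles follow the coverage definition", {
  v <- array(37:46, c(10, 1, 1))
  mask <- array(TRUE, c(10, 1, 1))
  p <- temperature_percentiles(v, mask)
  expect_equal(unname(p["T90"]), 38)  # reached in at least 9 of 10 voxels
  expect_equal(unname(p["T50"]), 42)
  expect_equal(unname(p["T10"]), 46)
  expect_true(p["T10"] >= p["T50"] && p["T50"] >= p["T90"])
  u <- array(40.5, c(4, 1, 1))
  pu <- temperature_percentiles(u, array(TRUE, c(4, 1, 1)))
  expect_true(all(pu == 40.5))
})

test_that("cumulative histograms are monotone and anchored at full volume", {
  set.seed(6)
  v <- array(rexp(1000), c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  h <- dvh_curve(v, mask, voxel_cc = 0.001)
  expect_equal(h$fraction[1], 1)
  expect_true(all(diff(h$fraction) <= 0))
  expect_equal(h$cc, h$fraction * 1000 * 0.001)
})

test_that("gamma index is exact on identity and uniform-offset cases", {
  g <- voxel_grid(c(7, 7, 7), c(1, 1, 1))
  set.seed(2)
  ref <- grid_like(g, array(runif(343, 1, 10), g$shape))
  res <- gamma_index_3d(ref, ref, low_cutoff = 0)
  expect_equal(max(res$gamma$values), 0)
  expect_equal(res$pass_rate, 100)

  uref <- grid_like(g, array(8, g$shape))
  shift <- grid_like(g, array(8 + 0.05 * 8, g$shape))
  res2 <- gamma_index_3d(uref, shift, dd_percent = 5, dta_mm = 0.5,
                         low_cutoff = 0)
  expect_equal(unname(as.vector(res2$gamma$values)), rep(1, 343),
               tolerance = 1e-12)
  expect_equal(res2$pass_rate, 100)
})

test_that("gamma matches an exhaustive-search oracle on a small grid", {
  g <- voxel_grid(c(9, 9, 9), c(1, 1, 1))
  set.seed(3)
  ref <- grid_like(g, array(runif(729, 0, 10), g$shape))
  ev <- grid_like(g, ref$values + array(rnorm(729, 0, 0.5), g$shape))
  dta <- 3
  res <- gamma_index_3d(ref, ev, dd_percent = 5, dta_mm = dta,
                        low_cutoff = 0, subsample = 1,
                        search_radius_factor = 10)
  ax <- grid_axes(g)
  pos <- as.matrix(expand.grid(ax$x, ax$y, ax$z))
  crit <- 0.05 * max(ref$values)
  rv <- as.numeric(ref$values); evv <- as.numeric(ev$values)
  oracle <- numeric(729)
  for (p in seq_len(729)) {
    d2 <- rowSums(sweep(pos, 2, pos[p, ])^2)
    keep <- d2 <= (10 * dta)^2
    oracle[p] <- sqrt(min((evv[p] - rv[keep])^2 / crit^2 + d2[keep] / dta^2))
  }
  expect_equal(as.numeric(res$gamma$values), oracle, tolerance = 1e-12)
})

test_that("gamma validates criteria and rasters", {
  g <- voxel_grid(c(5, 5, 5), c(1, 1, 1))
  a <- grid_like(g, array(1, g$shape))
  b <- voxel_grid(c(6, 5, 5), c(1, 1, 1), values = array(1, c(6, 5, 5)))
  expect_error(gamma_index_3d(a, b), "raster")
  expect_error(gamma_index_3d(a, a, dd_percent = 0), "positive")
})
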