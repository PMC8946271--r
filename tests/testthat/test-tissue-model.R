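test_that("bundled property table carries the reference tissue values", {
  tab <- tissue_table()
  row <- function(t) tab[tab$tissue == t, ]
  expect_identical(row("prostate")$sigma, 0.838)
  expect_identical(row("prostate")$eps_r, 120.1)
  expect_identical(row("prostate")$omega, 394)
  expect_identical(row("dielectric")$sigma, 1e-5)
  expect_identical(row("dielectric")$eps_r, 2.4)
  expect_identical(row("muscle")$omega, 40)
  expect_identical(row("urethra")$rho, 1102)
  expect_identical(row("rectum")$k, 0.557)
  expect_identical(row("bladder")$c, 3581)
  expect_identical(row("air")$sigma, 0)
  expect_identical(row("bone")$eps_r, 21.8)
  expect_identical(row("fat")$sigma, 0.061)
  expect_true(all(tab$rho >= 0 & tab$c >= 0 & tab$k >= 0 & tab$omega >= 0))
})

test_that("perfusion converts to SI volumetric units", {
  expect_equal(perfusion_si(40), 6.667e-7, tolerance = 1e-4)
  expect_equal(perfusion_si(0), 0)
  m <- small_model()
  pg <- property_grids(m)
  mus <- which(m$grid$values == tissue_labels[["muscle"]])[1]
  expect_equal(pg$omega_si[mus], 40e-6 / 60)
  pro <- which(m$grid$values == tissue_labels[["prostate"]])[1]
  expect_equal(pg$sigma[pro], 0.838)
  expect_equal(pg$eps_r[pro], 120.1)
})

test_that("phantom generation is reproducible and geometrically sound", {
  cfg <- small_config()
  m1 <- generate_phantom(cfg, seed = 3)
  m2 <- generate_phantom(cfg, seed = 3)
  expect_identical(m1$grid$values, m2$grid$values)
  expect_identical(m1$applicators, m2$applicators)
  m3 <- generate_phantom(cfg, seed = 4)
  expect_false(identical(m1$applicators, m3$applicators))

  # prostate volume in a plausible range for the configured ellipsoid
  vol_cc <- sum(organ_mask(m1, "prostate") | organ_mask(m1, "urethra")) *
    voxel_cc(m1$grid)
  expect_gt(vol_cc, 12); expect_lt(vol_cc, 22)

  # urethra lies inside the prostate ellipsoid
  ur <- which(organ_mask(m1, "urethra"), arr.ind = TRUE)
  w <- index_to_world(m1$grid, ur)
  s <- m1$semiaxes
  expect_true(all((w[, 1] / s[1])^2 + (w[, 2] / s[2])^2 + (w[, 3] / s[3])^2 <= 1))

  # one label per voxel means organ masks are pairwise disjoint
  organs <- c("prostate", "urethra", "rectum", "bladder")
  counts <- Reduce(`+`, lapply(organs, function(o) organ_mask(m1, o)))
  expect_true(all(counts <= 1))
  expect_true(all(vapply(organs, function(o) any(organ_mask(m1, o)), TRUE)))
})

test_that("an 18-applicator phantom carries 36 electrode segments", {
  m <- acc_model()
  expect_length(m$applicators, 18)
  expect_identical(nrow(electrode_table(m)), 36L)
  expect_true(all(vapply(m$applicators,
                         function(a) nrow(a$electrodes) == 2L, TRUE)))
  # 20 mm segments with a 5 mm gap, non-overlapping
  for (a in m$applicators) {
    expect_equal(a$electrodes$s_end - a$electrodes$s_start, c(20, 20))
    expect_equal(a$electrodes$s_start[2] - a$electrodes$s_end[1], 5)
  }
})

test_that("electrode rasterization is dense, disjoint and orientation-robust", {
  m <- small_model()
  ras <- rasterize_electrodes(m)
  expect_length(ras, 12)
  expect_true(all(lengths(ras) > 0))
  # the two electrodes of each applicator occupy disjoint voxel sets
  for (k in seq_len(6))
    expect_length(intersect(ras[[2 * k - 1]], ras[[2 * k]]), 0)

  # a 20 mm electrode on a 1 mm grid covers at least 20 voxels
  mz <- line_model(c(0, 0, -10), c(0, 0, 10))
  rz <- rasterize_electrodes(mz)
  expect_gte(length(rz[[1]]), 20)
  # rotating the applicator by 90 degrees preserves the count within 20%
  mx <- line_model(c(-10, 0, 0), c(10, 0, 0))
  rx <- rasterize_electrodes(mx)
  expect_lt(abs(length(rx[[1]]) - length(rz[[1]])) / length(rz[[1]]), 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(generate_phantom(small_config(spacing = c(6, 6, 6))),
               "electrode gap")
  expect_error(applicator("bad", c(0, 0, 0), c(0, 0, 40),
                          data.frame(s_start = c(0, 15), s_end = c(20, 35))),
               "overlap")
  m <- small_model()
  m2 <- m
  m2$grid$values[1] <- 99L
  expect_error(property_grids(m2), "lookup error")
})
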