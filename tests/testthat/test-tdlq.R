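test_that("thermal fold-change interpolates exponentially", {
  expect_equal(thermal_ratio(37, 5), 1.0)
  expect_equal(thermal_ratio(43, 2.4), 2.4)
  expect_equal(thermal_ratio(40, 6.8), sqrt(6.8))
  expect_equal(thermal_ratio(40, 6.8), 2.6077, tolerance = 1e-4)
  # extrapolation above Tref follows the same law
  expect_equal(thermal_ratio(46, 2), 2^1.5)
  expect_error(thermal_ratio(40, -1), "domain error")
})

test_that("presets carry the cell-line fold-changes and the mean is exact", {
  pc3 <- tdlq_preset("PC3"); du <- tdlq_preset("DU145")
  expect_identical(c(pc3$alpha_ratio, pc3$beta_ratio), c(2.4, 6.8))
  expect_identical(c(du$alpha_ratio, du$beta_ratio), c(0.8, 1.8))
  avg <- average_params(pc3, du)
  expect_identical(avg$alpha_ratio, 1.6)
  expect_identical(avg$beta_ratio, 4.3)
  bundled <- tdlq_preset("AVG")
  expect_identical(c(bundled$alpha_ratio, bundled$beta_ratio), c(1.6, 4.3))
  expect_identical(average_params(pc3, pc3)[c("alpha_ratio", "beta_ratio")],
                   pc3[c("alpha_ratio", "beta_ratio")])
  du2 <- tdlq_params(0.8, 1.8, Tref = 45)
  expect_error(average_params(pc3, du2), "validation error")
})

test_that("survival follows the temperature-scaled LQ model", {
  pc3 <- tdlq_preset("PC3")
  expect_equal(survival_fraction(0, 42, 0.15, 0.05, pc3), 1.0)
  expect_equal(survival_fraction(2, 37, 0.15, 0.05, pc3), exp(-0.5))
  expect_equal(survival_fraction(2, 43, 0.15, 0.05, pc3),
               exp(-0.15 * 2.4 * 2 - 0.05 * 6.8 * 4))
  expect_equal(survival_fraction(2, 43, 0.15, 0.05, pc3), 0.1249,
               tolerance = 1e-3)
  expect_error(survival_fraction(-1, 37, 0.15, 0.05, pc3), "domain error")
})

test_that("equivalent physical dose hits the closed-form anchor points", {
  for (nm in c("PC3", "DU145", "AVG", "NONE"))
    expect_equal(eqd_phys(10, 37, tdlq_preset(nm)), 10)
  expect_equal(eqd_phys(10, 43, tdlq_preset("PC3")),
               (3 * 2.4 * 10 + 6.8 * 100) / 13)
  expect_equal(eqd_phys(10, 43, tdlq_preset("PC3")), 57.846, tolerance = 1e-3)
  expect_equal(eqd_phys(10, 43, tdlq_preset("DU145")), (24 + 180) / 13)
  expect_equal(eqd_phys(10, 43, tdlq_preset("DU145")), 15.692, tolerance = 1e-3)
  expect_equal(eqd_phys(10, 40, tdlq_preset("PC3")),
               (3 * sqrt(2.4) * 10 + sqrt(6.8) * 100) / 13)
  expect_equal(eqd_phys(10, 40, tdlq_preset("PC3")), 23.635, tolerance = 1e-3)
})

test_that("equivalent dose is monotone and the no-sensitization preset is identity", {
  pc3 <- tdlq_preset("PC3")
  D <- seq(0.5, 20, by = 0.5)
  Tgrid <- seq(37, 47.5, by = 0.5)
  for (Tv in Tgrid) {
    e <- eqd_phys(D, Tv, pc3)
    expect_true(all(diff(e) > 0))          # increasing in D
  }
  for (d in c(1, 5, 13.5)) {
    e <- eqd_phys(d, Tgrid, pc3)
    expect_true(all(diff(e) > 0))          # increasing in T
  }
  none <- tdlq_preset("NONE")
  expect_equal(eqd_phys(D, 44.2, none), D)
  Tvec <- seq(47.5, 37, length.out = length(D))
  expect_equal(eqd_phys(D, Tvec, none), D)
})

test_that("equal-kill isodose curves are smooth and monotone decreasing", {
  pc3 <- tdlq_preset("PC3")
  tab <- eqd_table(c(5, 10), c(37, 43), pc3)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$eqd[tab$D == 10 & tab$T == 43], (72 + 680) / 13)
  expect_equal(tab$eqd[tab$T == 37], c(5, 10))
  Tgrid <- seq(37.5, 45, by = 0.5)
  # dose required to reach a fixed equivalent dose at each temperature
  d_req <- vapply(Tgrid, function(Tv)
    stats::uniroot(function(d) eqd_phys(d, Tv, pc3) - 13.5,
                   c(1e-3, 20))$root, numeric(1))
  expect_true(all(diff(d_req) < 0))
  expect_true(all(d_req < 13.5))
})

test_that("grid-level equivalent dose respects tissue assignment", {
  m <- small_model()
  D <- grid_like(m$grid, array(10, m$grid$shape))
  Tgrid <- grid_like(m$grid, array(43, m$grid$shape))
  pmap <- tissue_param_map(tdlq_preset("PC3"), oar_mode = "none")
  eq <- eqd_phys_grid(D, Tgrid, m, pmap)
  pro <- organ_mask(m, "prostate")
  rec <- organ_mask(m, "rectum")
  expect_equal(unique(eq$values[pro]), (3 * 2.4 * 10 + 6.8 * 100) / 13)
  expect_equal(unique(eq$values[rec]), 10)  # no normal-tissue sensitization
  pmap_w <- tissue_param_map(tdlq_preset("PC3"), oar_mode = "worst")
  eq_w <- eqd_phys_grid(D, Tgrid, m, pmap_w)
  expect_equal(unique(eq_w$values[rec]), (3 * 2.4 * 10 + 6.8 * 100) / 13)
})
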