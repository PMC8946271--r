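capacitor_solve <- function(h, n, a = 5, b = 20, sigma = 0.5) {
  g <- voxel_grid(c(n, n, n), c(h, h, h))
  ax <- grid_axes(g)
  R <- sqrt(outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+"))
  dir <- R <= a | R >= b
  fix <- array(0, g$shape); fix[R <= a] <- 1
  V <- solve_quasistatic(g, array(sigma + 0i, g$shape), dir, fix)
  list(grid = g, R = R, V = V, a = a, b = b)
}

test_that("potential solve matches the spherical-capacitor closed form", {
  cs <- capacitor_solve(0.5, 85)
  analytic <- (1 / cs$R - 1 / cs$b) / (1 / cs$a - 1 / cs$b)
  sel <- cs$R > 8 & cs$R < 16  # away from the staircased shells
  err <- abs(Re(cs$V$values[sel]) - analytic[sel]) / analytic[sel]
  expect_lt(max(err), 0.05)

  # field magnitude against the analytic derivative (1/r^2 profile, V/m)
  E <- efield(cs$V)
  Emag <- sqrt(Mod(E$Ex)^2 + Mod(E$Ey)^2 + Mod(E$Ez)^2)
  Ean <- 1000 / (cs$R^2 * (1 / cs$a - 1 / cs$b))
  expect_lt(max(abs(Emag[sel] - Ean[sel]) / Ean[sel]), 0.07)
})

test_that("discretization error decreases under grid refinement", {
  err_at <- function(h, n) {
    cs <- capacitor_solve(h, n)
    analytic <- (1 / cs$R - 1 / cs$b) / (1 / cs$a - 1 / cs$b)
    sel <- cs$R > 8 & cs$R < 16
    max(abs(Re(cs$V$values[sel]) - analytic[sel]) / analytic[sel])
  }
  expect_lt(err_at(0.5, 85), err_at(1, 49))
})

test_that("real conductivity yields a real solution, linear in the drive", {
  g <- voxel_grid(c(25, 25, 25), c(1, 1, 1))
  ax <- grid_axes(g)
  R <- sqrt(outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+"))
  dir <- R <= 3 | R >= 11
  fix <- array(0, g$shape); fix[R <= 3] <- 1
  adm <- array(0.3 + 0i, g$shape)
  V1 <- solve_quasistatic(g, adm, dir, fix)
  expect_lt(max(abs(Im(V1$values))), 1e-10)
  V2 <- solve_quasistatic(g, adm, dir, 2 * fix)
  expect_equal(V2$values, 2 * V1$values, tolerance = 1e-6)
})

test_that("gradient operator handles constants, slopes and units", {
  g <- voxel_grid(c(9, 9, 9), c(1, 1, 1))
  expect_true(all(unlist(efield(grid_like(g, 3))) == 0))
  ax <- grid_axes(g)
  slope <- 0.25  # V/mm
  V <- grid_like(g, array(ax$x * slope, g$shape))
  E <- efield(V)
  expect_equal(unname(as.vector(E$Ex)), rep(-250, 729), tolerance = 1e-12)
  expect_true(all(E$Ey == 0) && all(E$Ez == 0))
})

test_that("power density follows the coherent quadratic form", {
  dims <- c(4, 4, 4)
  zero <- array(0i, dims)
  E100 <- list(Ex = array(100 + 0i, dims), Ey = zero, Ez = zero)
  sig <- array(0.838, dims)
  P <- power_density(list(E100), 1, sig)
  expect_equal(P[1], 0.838 * 100^2 / 2)  # 4190 W/m^3
  expect_equal(power_density(list(E100), 2, sig), 4 * P)
  # equal and opposite amplitudes cancel coherently
  expect_true(all(power_density(list(E100, E100), c(1, -1), sig) == 0))
  expect_error(power_density(list(E100), c(1, 2), sig), "dimension error")
})

test_that("diagonal unit powers reproduce the full form on orthogonal fields", {
  dims <- c(6, 4, 4)
  zero <- array(0i, dims)
  E1 <- list(Ex = zero, Ey = zero, Ez = zero)
  E2 <- list(Ex = zero, Ey = zero, Ez = zero)
  E1$Ex[1:3, , ] <- 50 + 20i      # disjoint spatial supports
  E2$Ey[4:6, , ] <- 30 - 10i
  sig <- array(0.6, dims)
  up <- unit_power_per_electrode(list(E1, E2), sig)
  v <- c(1.3, 0.7)
  expect_equal(v[1]^2 * up[[1]] + v[2]^2 * up[[2]],
               power_density(list(E1, E2), v, sig), tolerance = 1e-12)
  zeroE <- list(Ex = zero, Ey = zero, Ez = zero)
  expect_true(all(unit_power_per_electrode(list(zeroE), sig)[[1]] == 0))
})

test_that("per-electrode phantom solves satisfy the Dirichlet contract", {
  m <- small_model()
  ras <- rasterize_electrodes(m)
  props <- property_grids(m)
  V <- solve_potential(m, 1, ras = ras, props = props)
  expect_equal(unname(V$values[ras[[1]]]), rep(1 + 0i, length(ras[[1]])))
  expect_true(all(V$values[ras[[2]]] == 0))
  expect_true(all(V$values[boundary_mask(m$grid$shape)] == 0))
  expect_error(solve_potential(m, 99, ras = ras, props = props), "range")
})
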