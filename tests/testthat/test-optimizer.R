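toy_problem <- function(n_el = 1, Mt = NULL, prostate_D = NULL) {
  if (is.null(prostate_D)) prostate_D <- c(rep(20, 93), rep(5, 7))
  np <- length(prostate_D)
  n_union <- np + 3
  if (is.null(Mt)) Mt <- matrix(0, n_union, n_el)
  structure(list(
    n_el = n_el, Tb = 37, Tmax = 47.5, W = 1e3, Dp = 10,
    protocol = bt_protocol(10),
    lower = rep(0, n_el), upper = rep(3, n_el),
    Mt = Mt, union_idx = seq_len(n_union),
    organs = list(
      prostate = list(pos = seq_len(np), D = prostate_D),
      urethra = list(pos = np + 1, D = 10),
      rectum = list(pos = np + 2, D = 5),
      bladder = list(pos = np + 3, D = 1)),
    tumor = tdlq_preset("PC3"), oar = tdlq_preset("PC3"), oar_mode = "worst",
    limits = list(V100 = 95, urethra_D0.1cc = 20, rectum_D1cc = 20,
                  bladder_D1cc = 20, Tmax = 47.5),
    voxel_cc = 1,
    objectives = data.frame(name = c("urethra_D0.1cc", "rectum_D1cc",
                                     "prostate_V150"),
                            goal = c(0, 0, 30), weight = c(1, 1, 0.01))
  ), class = "plan_problem")
}

test_that("penalties and scores follow the penalized-objective definition", {
  p <- toy_problem()
  e <- evaluate_objective(0, p)
  # coverage 93% against a high-pass limit of 95% costs W * 2
  expect_equal(unname(e$penalties["V100"]), 2)
  expect_equal(unname(e$metrics$V100), 93)
  # urethra dose 10 Gy with goal 0 and weight 1 scores 10
  expect_equal(unname(e$scores["urethra_D0.1cc"]), 10)
  expect_equal(e$omega,
               1e3 * 2 + 10 + 5 + 0.01 * (93 - 30))
  expect_false(e$feasible)
  expect_error(evaluate_objective(c(0, 0), p), "dimension error")
})

test_that("objective vanishes exactly when constraints hold and goals are met", {
  p <- toy_problem()
  e0 <- evaluate_objective(0, p)
  p$limits <- list(V100 = e0$metrics$V100,
                   urethra_D0.1cc = e0$metrics$urethra_D0.1cc,
                   rectum_D1cc = e0$metrics$rectum_D1cc,
                   bladder_D1cc = e0$metrics$bladder_D1cc, Tmax = 47.5)
  p$objectives$goal <- c(e0$metrics$urethra_D0.1cc, e0$metrics$rectum_D1cc,
                         e0$metrics$V150)
  e <- evaluate_objective(0, p)
  expect_equal(e$omega, 0)
  expect_true(e$feasible)
})

test_that("exceeding the temperature ceiling is penalized", {
  p <- toy_problem(n_el = 1, Mt = matrix(c(11, rep(0, 102)), ncol = 1))
  e <- evaluate_objective(1, p)
  expect_equal(unname(e$metrics$Tmax), 48)
  expect_equal(unname(e$penalties["Tmax"]), 0.5)
  expect_false(e$feasible)
  e0 <- evaluate_objective(0, p)
  expect_equal(unname(e0$penalties["Tmax"]), 0)
})

test_that("particle swarm recovers a convex minimum and is reproducible", {
  vstar <- c(0.3, -0.2, 0.8, 0.1, -0.5)
  fn <- function(v) sum((v - vstar)^2)
  res <- pso_minimize(fn, rep(-1, 5), rep(1, 5),
                      pso_control(n_particles = 30, maxit = 200,
                                  stagnation = 200), seed = 42)
  expect_lt(sqrt(sum((res$par - vstar)^2)), 1e-2)
  res2 <- pso_minimize(fn, rep(-1, 5), rep(1, 5),
                       pso_control(n_particles = 30, maxit = 200,
                                   stagnation = 200), seed = 42)
  expect_identical(res, res2)
  expect_true(all(diff(res$trace) <= 0))
  expect_error(pso_minimize(fn, numeric(0), numeric(0)), "zero-dimensional")
})

test_that("constrained two-electrode optimum matches exhaustive grid search", {
  np <- 40
  Mt <- matrix(0, np + 3, 2)
  Mt[1:20, 1] <- 1; Mt[1, 1] <- 2.5          # ceiling binds on channel 1
  Mt[21:40, 2] <- 1
  p <- toy_problem(n_el = 2, Mt = Mt, prostate_D = rep(8, np))
  p$limits$V100 <- 95
  fn <- function(v) evaluate_objective(v, p)$search_omega
  opt <- pso_optimize(p, pso_control(n_particles = 30, maxit = 150,
                                     stagnation = 150), seed = 5)
  vg <- seq(0, 3, length.out = 121)
  grid_vals <- outer(vg, vg, Vectorize(function(a, b) fn(c(a, b))))
  expect_lt(evaluate_objective(opt$v, p)$search_omega,
            min(grid_vals) + 1e-2)
  expect_lte(opt$metrics$Tmax, 47.5 + 1e-8)
})

test_that("limits from the BT-only plan make the unheated plan feasible", {
  m <- small_model()
  bt <- small_bt()
  limits <- limits_from_bt_plan(bt$dose, m)
  expect_equal(limits$Tmax, 47.5)
  expect_gte(limits$V100, 95)
  prob <- plan_problem(m, small_bases(), bt$dose, limits, tdlq_preset("AVG"))
  e <- evaluate_objective(rep(0, prob$n_el), prob)
  expect_true(e$feasible)
  expect_equal(e$metrics$V100, limits$V100)
  expect_equal(e$metrics$urethra_D0.1cc, limits$urethra_D0.1cc)
  expect_equal(e$metrics$rectum_D1cc, limits$rectum_D1cc)
  # scaled-down dose at baseline temperature violates the coverage limit
  prob2 <- plan_problem(m, small_bases(), scale_dose(bt$dose, 0.8), limits,
                        tdlq_preset("AVG"))
  e2 <- evaluate_objective(rep(0, prob2$n_el), prob2)
  expect_gt(unname(e2$penalties["V100"]), 0)
})

test_that("amplitude bounds are calibrated to the temperature ceiling", {
  basis <- small_bases()
  vmax <- amplitude_bounds(basis$delta_t)
  expect_length(vmax, 12)
  for (i in c(1, 7)) {
    peak <- 37 + unname(vmax[i])^2 * max(basis$delta_t[[i]])
    expect_equal(peak, 47.5)
  }
})

test_that("monotone heating: raising any amplitude never cools a voxel", {
  dt <- small_bases()$delta_t
  set.seed(8)
  v <- runif(12, 0, 1)
  T1 <- superpose_temperature(dt, v)
  v2 <- v; v2[4] <- v2[4] + 0.5
  T2 <- superpose_temperature(dt, v2)
  expect_true(all(T2 - T1 >= -1e-12))
})

test_that("dose-scaling study records coverage and temperature trends", {
  m <- small_model()
  tab <- dose_scaling_study(m, small_bases(), small_bt()$dose,
                            scalings = c(0.8, 0.9), presets = "AVG",
                            control = pso_control(n_particles = 25,
                                                  maxit = 80,
                                                  stagnation = 40),
                            seed = 3)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("V100", "T10", "T50", "T90", "urethra_D0.1cc_none",
                    "feasible") %in% names(tab)))
  # more physical dose never hurts equivalent coverage
  expect_gte(tab$V100[tab$scaling == 0.9] + 0.5,
             tab$V100[tab$scaling == 0.8])
  # lower physical dose demands more heat
  expect_gte(tab$T10[tab$scaling == 0.8] + 0.1,
             tab$T10[tab$scaling == 0.9])
  # no-sensitization OAR metrics scale with the physical dose
  bt <- small_bt()
  vcc <- voxel_cc(m$grid)
  ur_bt <- dose_at_volume_cc(bt$dose$values, organ_mask(m, "urethra"),
                             0.1, vcc)
  expect_equal(tab$urethra_D0.1cc_none, tab$scaling * ur_bt,
               tolerance = 1e-9)
})
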