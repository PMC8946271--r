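#' Precompute the per-electrode field and temperature bases
#'
#' Runs the full per-electrode chain once per electrode: potential solve,
#' E-field, unit-amplitude power density and steady-state temperature
#' elevation.  The result is reused by every optimizer evaluation, the
#' superposition validation and the dose-scaling study.
#'
#' @param model a `tbt_model`.
#' @param tol,maxit solver settings shared by the field and bioheat solves.
#' @param keep_potentials keep the complex potential grids (needed by the
#'   coupled reference recalculation).
#' @param verbose print progress messages.
#' @return object of class `electrode_basis`: list with `electrodes`
#'   (table), `ras` (voxel index sets), `unit_powers`, `delta_t`,
#'   `potentials` (optional), `props`, and solver settings.
#' @export
precompute_bases <- function(model, tol = 1e-8, maxit = 20000L,
                             keep_potentials = TRUE, verbose = FALSE) {
  props <- property_grids(model)
  ras <- rasterize_electrodes(model)
  n <- length(ras)
  pots <- if (keep_potentials) vector("list", n) else NULL
  unit_powers <- vector("list", n)
  names(unit_powers) <- names(ras)
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("field solve %d/%d", i, n))
    V <- solve_potential(model, i, ras = ras, props = props,
                         tol = tol, maxit = maxit)
    E <- efield(V)
    unit_powers[[i]] <- props$sigma / 2 *
      (Mod(E$Ex)^2 + Mod(E$Ey)^2 + Mod(E$Ez)^2)
    if (keep_potentials) pots[[i]] <- V$values
  }
  delta_t <- precompute_delta_t(model, unit_powers, props,
                                tol = tol, maxit = maxit, verbose = verbose)
  structure(list(electrodes = electrode_table(model), ras = ras,
                 unit_powers = unit_powers, delta_t = delta_t,
                 potentials = pots, props = props,
                 tol = tol, maxit = maxit),
            class = "electrode_basis")
}

#' E-field basis reconstructed from stored potentials
#' @param model a `tbt_model`.
#' @param basis an `electrode_basis` with potentials kept.
#' @return list of per-electrode E-fields.
#' @export
basis_efields <- function(model, basis) {
  if (is.null(basis$potentials))
    stop("basis was computed with keep_potentials = FALSE")
  lapply(basis$potentials, function(v) efield(grid_like(model$grid, v)))
}

#' Amplitude upper bounds calibrated to the temperature ceiling
#'
#' Per-electrode bound such that a single electrode at full drive reaches
#' the maximum tolerated temperature locally:
#' `vmax_i = sqrt((Tmax - Tb) / max dT_i)`.
#'
#' @param delta_t list of unit-amplitude elevation arrays (K).
#' @param Tmax temperature ceiling (degrees C).
#' @param Tb baseline temperature (degrees C).
#' @return numeric vector of upper bounds.
#' @export
amplitude_bounds <- function(delta_t, Tmax = 47.5, Tb = 37) {
  vapply(delta_t, function(d) sqrt((Tmax - Tb) / max(d)), numeric(1))
}

#' Constraint limits from the BT-only plan
#'
#' Evaluates the original (unscaled) BT-only dose distribution at baseline
#' temperature and returns its achieved metric values as the constraint
#' limits of the combined-plan optimization: the BT-only `V100` becomes the
#' high-pass coverage limit and the BT-only urethra `D0.1cc`, rectum `D1cc`
#' and bladder `D1cc` become low-pass limits.  The temperature ceiling is a
#' fixed low-pass limit.
#'
#' @param bt_dose original BT-only dose `voxel_grid` (Gy).
#' @param model a `tbt_model`.
#' @param protocol a [bt_protocol()].
#' @param Tmax temperature ceiling (degrees C).
#' @return named list of limits.
#' @export
limits_from_bt_plan <- function(bt_dose, model, protocol = bt_protocol(),
                                Tmax = 47.5) {
  for (org in c("prostate", "urethra", "rectum", "bladder"))
    if (!any(organ_mask(model, org)))
      stop("configuration error: organ missing from model: ", org)
  vcc <- voxel_cc(bt_dose)
  list(
    V100 = volume_fraction_at(bt_dose$values, organ_mask(model, "prostate"),
                              protocol$Dp),
    urethra_D0.1cc = dose_at_volume_cc(bt_dose$values,
                                       organ_mask(model, "urethra"), 0.1, vcc),
    rectum_D1cc = dose_at_volume_cc(bt_dose$values,
                                    organ_mask(model, "rectum"), 1, vcc),
    bladder_D1cc = dose_at_volume_cc(bt_dose$values,
                                     organ_mask(model, "bladder"), 1, vcc),
    Tmax = Tmax)
}

#' Assemble a combined-plan optimization problem
#'
#' Precomputes everything an objective evaluation needs: the per-electrode
#' elevation matrix restricted to the organ masks plus a heating envelope
#' (the voxels whose elevation could exceed a small threshold under any
#' feasible amplitude vector, so the temperature ceiling is checked only
#' where it can bind), per-organ dose vectors from the scaled plan, and the
#' constraint/objective bookkeeping.
#'
#' @param model a `tbt_model`.
#' @param basis an `electrode_basis`.
#' @param dose_scaled scaled physical dose `voxel_grid` (Gy).
#' @param limits constraint limits from [limits_from_bt_plan()].
#' @param tumor_params target [tdlq_params()].
#' @param oar_mode normal-tissue sensitization: `"worst"` (equal to tumor)
#'   or `"none"`.
#' @param protocol a [bt_protocol()] (prescription dose and criteria).
#' @param W penalty weight.
#' @param Tmax temperature ceiling (degrees C).
#' @param vmax amplitude upper bounds; default calibrated by
#'   [amplitude_bounds()].
#' @param envelope_K elevation threshold (K) defining the heating envelope.
#' @return object of class `plan_problem`.
#' @export
plan_problem <- function(model, basis, dose_scaled, limits,
                         tumor_params, oar_mode = c("worst", "none"),
                         protocol = bt_protocol(), W = 1e3, Tmax = 47.5,
                         vmax = NULL, envelope_K = 0.2) {
  oar_mode <- match.arg(oar_mode)
  stopifnot_same_raster(model$grid, dose_scaled)
  delta_t <- basis$delta_t
  if (is.null(vmax)) vmax <- amplitude_bounds(delta_t, Tmax, model$blood$Tb)

  U <- superpose_temperature(delta_t, vmax, Tb = 0)  # max attainable elevation
  env <- U >= envelope_K
  organs <- c("prostate", "urethra", "rectum", "bladder")
  masks <- lapply(organs, function(o) organ_mask(model, o))
  names(masks) <- organs
  union <- env
  for (m in masks) union <- union | m
  union_idx <- which(union)
  Mt <- vapply(delta_t, function(d) d[union_idx],
               numeric(length(union_idx)))
  organ_info <- lapply(organs, function(o) {
    pos <- match(which(masks[[o]]), union_idx)
    list(pos = pos, D = dose_scaled$values[masks[[o]]])
  })
  names(organ_info) <- organs

  oar_params <- if (oar_mode == "worst") tumor_params else
    tdlq_preset("NONE", alpha_beta_37 = tumor_params$alpha_beta_37)
  structure(list(
    n_el = length(delta_t), Tb = model$blood$Tb, Tmax = Tmax, W = W,
    Dp = protocol$Dp, protocol = protocol,
    lower = rep(0, length(delta_t)), upper = vmax,
    Mt = Mt, union_idx = union_idx, organs = organ_info,
    tumor = tumor_params, oar = oar_params, oar_mode = oar_mode,
    limits = limits, voxel_cc = voxel_cc(dose_scaled),
    # objective rows: urethra D0.1cc -> 0 (w 1), rectum D1cc -> 0 (w 1),
    # prostate V150 -> 30 % of volume (w 0.01)
    objectives = data.frame(name = c("urethra_D0.1cc", "rectum_D1cc",
                                     "prostate_V150"),
                            goal = c(0, 0, 30), weight = c(1, 1, 0.01))
  ), class = "plan_problem")
}

eqd_organ <- function(D, T, params) {
  ab <- params$alpha_beta_37
  x <- (T - 37) / (params$Tref - 37)
  ra <- exp(x * log(params$alpha_ratio))
  rb <- exp(x * log(params$beta_ratio))
  (ab * ra * D + rb * D^2) / (ab + D)
}

#' Evaluate the penalized plan objective
#'
#' Computes the temperature by superposition, the per-organ equivalent
#' physical dose, the dose-volume metrics, and the penalized objective
#' `Omega = W * sum(PF) + sum(SF)` with `PF_i = max(0, p_i (C_i - L_i))`
#' (polarity +1 for low-pass, -1 for high-pass constraints) and
#' `SF_j = w_j (O_j - G_j)`.
#'
#' @param v amplitude vector (length `n_el`).
#' @param problem a [plan_problem()].
#' @return list with `omega`, `metrics`, `penalties`, `scores`, `feasible`.
#' @export
evaluate_objective <- function(v, problem) {
  p <- problem
  if (length(v) != p$n_el) stop("dimension error: amplitude vector length")
  elev <- as.numeric(p$Mt %*% (v * v))
  Tmax_val <- p$Tb + max(elev)

  Tp <- p$Tb + elev[p$organs$prostate$pos]
  eqd_p <- eqd_organ(p$organs$prostate$D, Tp, p$tumor)
  oar_eqd <- lapply(c("urethra", "rectum", "bladder"), function(o) {
    To <- p$Tb + elev[p$organs[[o]]$pos]
    eqd_organ(p$organs[[o]]$D, To, p$oar)
  })
  names(oar_eqd) <- c("urethra", "rectum", "bladder")

  np <- length(eqd_p)
  metrics <- list(
    V100 = 100 * sum(eqd_p >= p$Dp) / np,
    V150 = 100 * sum(eqd_p >= 1.5 * p$Dp) / np,
    V200 = 100 * sum(eqd_p >= 2.0 * p$Dp) / np,
    urethra_D0.1cc = d_hot(oar_eqd$urethra, 0.1 / p$voxel_cc),
    rectum_D1cc = d_hot(oar_eqd$rectum, 1 / p$voxel_cc),
    bladder_D1cc = d_hot(oar_eqd$bladder, 1 / p$voxel_cc),
    Tmax = Tmax_val)

  penalties <- c(
    V100 = max(0, -(metrics$V100 - p$limits$V100)),
    urethra_D0.1cc = max(0, metrics$urethra_D0.1cc - p$limits$urethra_D0.1cc),
    rectum_D1cc = max(0, metrics$rectum_D1cc - p$limits$rectum_D1cc),
    bladder_D1cc = max(0, metrics$bladder_D1cc - p$limits$bladder_D1cc),
    Tmax = max(0, Tmax_val - p$limits$Tmax))
  obs <- c(metrics$urethra_D0.1cc, metrics$rectum_D1cc, metrics$V150)
  scores <- p$objectives$weight * (obs - p$objectives$goal)
  names(scores) <- p$objectives$name
  omega <- p$W * sum(penalties) + sum(scores)
  # continuous search surrogate for the stepwise V100 penalty: the coverage
  # constraint V100 >= L is equivalent to the EQD at the L-coverage order
  # statistic reaching Dp, which is continuous in the amplitudes; the term
  # vanishes exactly when the constraint holds, so the reported objective
  # is unchanged at feasible points
  qL <- d_hot(eqd_p, p$limits$V100 / 100 * np)
  search_omega <- omega + p$W * max(0, p$Dp - qL)
  list(omega = omega, search_omega = search_omega,
       metrics = metrics, penalties = penalties, scores = scores,
       feasible = all(penalties <= 1e-9))
}

# hottest-m-voxels metric on an unsorted vector (m may be fractional)
d_hot <- function(x, m) {
  d <- sort(x, decreasing = TRUE)
  n <- length(d)
  if (m <= 1) return(d[1])
  lo <- floor(m); hi <- ceiling(m)
  if (lo == hi || hi > n) return(d[min(lo, n)])
  d[lo] + (m - lo) * (d[hi] - d[lo])
}

#' Physics-informed warm-start amplitudes
#'
#' Inverts the TDLQ relation voxel-wise on the prostate to find the
#' temperature elevation each voxel needs for its scaled physical dose to
#' reach the prescription in equivalent dose, drops the hardest voxels that
#' the coverage limit allows to stay cold, and solves a nonnegative
#' least-squares problem for the squared amplitudes against the
#' per-electrode elevation basis.  The result (clipped to the bounds and to
#' the temperature ceiling) is a deterministic starting point near the
#' feasible region.
#'
#' @param problem a [plan_problem()].
#' @param max_rows subsample cap on the least-squares rows.
#' @return amplitude vector (length `n_el`).
#' @export
warm_start_amplitudes <- function(problem, max_rows = 4000) {
  p <- problem
  D <- p$organs$prostate$D
  tum <- p$tumor
  # bisect for x = (T - 37)/(Tref - 37) with EQD(D, x) = Dp
  need <- rep(0, length(D))
  cold <- which(D < p$Dp & D > 0)
  if (length(cold)) {
    ab <- tum$alpha_beta_37
    la <- log(tum$alpha_ratio); lb <- log(tum$beta_ratio)
    Dc <- D[cold]
    lo <- rep(0, length(Dc)); hi <- rep(2, length(Dc))
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      val <- (ab * exp(mid * la) * Dc + exp(mid * lb) * Dc^2) / (ab + Dc)
      up <- val < p$Dp
      lo[up] <- mid[up]; hi[!up] <- mid[!up]
    }
    need[cold] <- (lo + hi) / 2 * (tum$Tref - 37)
  }
  # the coverage limit lets the hardest (100 - L)% stay cold
  n_allow <- floor((1 - p$limits$V100 / 100) * length(D))
  if (n_allow > 0) {
    hard <- order(need, decreasing = TRUE)[seq_len(n_allow)]
    need[hard] <- 0
  }
  rows <- which(need > 0)
  if (!length(rows)) return(rep(0, p$n_el))
  if (length(rows) > max_rows)
    rows <- rows[round(seq(1, length(rows), length.out = max_rows))]
  A <- p$Mt[p$organs$prostate$pos[rows], , drop = FALSE]
  fit <- pracma::lsqnonneg(A, need[rows])
  v <- sqrt(fit$x)
  v <- pmin(v, p$upper)
  peak <- max(p$Mt %*% (v * v))
  if (peak > 0) v <- v * min(1, sqrt(0.98 * (p$Tmax - p$Tb) / peak))
  v
}

#' Particle-swarm settings
#'
#' Standard global-best PSO with constriction-style coefficients.
#'
#' @param n_particles swarm size.
#' @param inertia inertia weight.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param vclamp velocity clamp as a fraction of the bound range.
#' @param maxit maximum iterations.
#' @param stagnation stop early after this many iterations without
#'   improvement of the global best.
#' @return list of class `pso_control`.
#' @export
pso_control <- function(n_particles = 50, inertia = 0.7298,
                        c1 = 1.49618, c2 = 1.49618, vclamp = 0.2,
                        maxit = 300, stagnation = 50) {
  structure(as.list(environment()), class = "pso_control")
}

#' Global-best particle-swarm minimization
#'
#' Minimizes `fn` over a box, positions clipped to the bounds, with a
#' seeded, fully reproducible swarm.
#'
#' @param fn objective, takes a numeric vector, returns a scalar.
#' @param lower,upper bound vectors (finite, equal length).
#' @param control a [pso_control()].
#' @param seed integer seed.
#' @param init optional matrix of starting positions (rows) injected into
#'   the initial swarm (clipped to bounds).
#' @return list with `par`, `value`, `trace` (global best per iteration),
#'   `iterations`, `evaluations`.
#' @export
pso_minimize <- function(fn, lower, upper, control = pso_control(), seed = 1,
                         init = NULL) {
  d <- length(lower)
  if (d == 0) stop("validation error: zero-dimensional problem")
  if (length(upper) != d || any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite and of equal length")
  ctl <- control
  with_seed(seed, {
    rng <- upper - lower
    np <- ctl$n_particles
    X <- matrix(stats::runif(np * d), np, d) * rep(rng, each = np) +
      rep(lower, each = np)
    if (!is.null(init)) {
      init <- rbind(init)
      k <- min(nrow(init), np)
      X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
    }
    Vm <- matrix(stats::runif(np * d, -1, 1), np, d) *
      rep(ctl$vclamp * rng, each = np)
    pbest <- X
    pval <- apply(X, 1, fn)
    gi <- which.min(pval)
    gbest <- X[gi, ]; gval <- pval[gi]
    trace <- numeric(0)
    nev <- np
    stag <- 0L
    it <- 0L
    vmaxc <- ctl$vclamp * rng
    while (it < ctl$maxit && stag < ctl$stagnation) {
      it <- it + 1L
      r1 <- matrix(stats::runif(np * d), np, d)
      r2 <- matrix(stats::runif(np * d), np, d)
      Vm <- ctl$inertia * Vm +
        ctl$c1 * r1 * (pbest - X) +
        ctl$c2 * r2 * (rep(1, np) %o% gbest - X)
      Vm <- pmin(pmax(Vm, rep(-vmaxc, each = np)), rep(vmaxc, each = np))
      X <- X + Vm
      X <- pmin(pmax(X, rep(lower, each = np)), rep(upper, each = np))
      fv <- apply(X, 1, fn)
      nev <- nev + np
      imp <- fv < pval
      pbest[imp, ] <- X[imp, , drop = FALSE]
      pval[imp] <- fv[imp]
      gi <- which.min(pval)
      if (pval[gi] < gval) {
        gval <- pval[gi]; gbest <- pbest[gi, ]; stag <- 0L
      } else stag <- stag + 1L
      trace <- c(trace, gval)
    }
    list(par = gbest, value = gval, trace = trace, iterations = it,
         evaluations = nev)
  })
}

#' Optimize electrode amplitudes for a combined plan
#'
#' Minimizes the penalized objective of [evaluate_objective()] over the
#' amplitude box with [pso_minimize()] (on the continuous search surrogate),
#' optionally polishes the swarm's best point with a bounded Nelder-Mead
#' local search, then recomputes the full metric report at the best
#' amplitudes (never trusting cached swarm values).
#'
#' @param problem a [plan_problem()].
#' @param control a [pso_control()].
#' @param seed integer seed (mandatory for reproducibility).
#' @param polish maximum Nelder-Mead polish evaluations (0 disables).
#' @return object of class `opt_result`: `v` (best amplitudes), `omega`,
#'   `trace`, `metrics`, `penalties`, `scores`, `feasible`, `seed`.
#' @export
pso_optimize <- function(problem, control = pso_control(), seed = 1,
                         polish = 3000) {
  clampfn <- function(v) pmin(pmax(v, problem$lower), problem$upper)
  fn <- function(v) evaluate_objective(v, problem)$search_omega
  ws <- warm_start_amplitudes(problem)
  init <- rbind(ws, outer(c(0.85, 0.95, 1.05, 1.15), ws), 0)
  res <- pso_minimize(fn, problem$lower, problem$upper, control, seed,
                      init = init)
  best <- res$par
  if (polish > 0) {
    pol <- stats::optim(best, function(v) fn(clampfn(v)),
                        method = "Nelder-Mead",
                        control = list(maxit = polish))
    if (pol$value < res$value) best <- clampfn(pol$par)
  }
  final <- evaluate_objective(best, problem)
  structure(list(v = best, omega = final$omega, trace = res$trace,
                 metrics = final$metrics, penalties = final$penalties,
                 scores = final$scores, feasible = final$feasible,
                 iterations = res$iterations, evaluations = res$evaluations,
                 seed = seed),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> omega %.4g, feasible: %s, V100 %.1f%%, Tmax %.2f C\n",
              x$omega, x$feasible, x$metrics$V100, x$metrics$Tmax))
  invisible(x)
}

#' Dose-scaling study
#'
#' For each physical dose scaling and thermoradiobiological preset, scale
#' the BT-only plan, optimize the electrode amplitudes against the BT-only
#' constraint limits, and record the coverage, temperature and OAR metrics
#' under both normal-tissue sensitization assumptions.
#'
#' @param model a `tbt_model`.
#' @param basis an `electrode_basis`.
#' @param bt_dose original (unscaled) BT-only dose `voxel_grid`.
#' @param scalings dose scale factors (fractions of the original plan).
#' @param presets preset names (see [tdlq_preset()]).
#' @param protocol a [bt_protocol()].
#' @param control a [pso_control()].
#' @param seed integer seed; each (scaling, preset) run gets a distinct
#'   derived seed.
#' @param verbose print progress.
#' @return data.frame, one row per (scaling, preset), with V100/V150/V200,
#'   T10/T50/T90 of the prostate, OAR metrics in the worst-case mode and in
#'   the no-sensitization mode, feasibility and omega.
#' @export
dose_scaling_study <- function(model, basis, bt_dose,
                               scalings = seq(0.70, 0.95, by = 0.05),
                               presets = c("PC3", "DU145", "AVG"),
                               protocol = bt_protocol(),
                               control = pso_control(), seed = 1,
                               verbose = FALSE) {
  limits <- limits_from_bt_plan(bt_dose, model, protocol)
  rows <- list()
  run <- 0L
  for (preset in presets) {
    tumor <- tdlq_preset(preset)
    for (s in scalings) {
      run <- run + 1L
      if (verbose)
        message(sprintf("scaling %.0f%% preset %s", 100 * s, preset))
      ds <- scale_dose(bt_dose, s)
      prob <- plan_problem(model, basis, ds, limits, tumor,
                           oar_mode = "worst", protocol = protocol)
      opt <- pso_optimize(prob, control, seed = seed + run)
      rows[[run]] <- study_row(model, basis, ds, prob, opt, s, preset,
                               protocol)
    }
  }
  do.call(rbind, rows)
}

study_row <- function(model, basis, ds, prob, opt, s, preset, protocol) {
  m <- opt$metrics
  # temperatures and no-sensitization OAR metrics recomputed from v*
  elev <- as.numeric(prob$Mt %*% (opt$v^2))
  Tpr <- prob$Tb + elev[prob$organs$prostate$pos]
  tp <- sort(Tpr, decreasing = TRUE)
  n <- length(tp)
  perc <- function(pp) {
    mm <- pp / 100 * n
    if (mm <= 1) return(tp[1])
    lo <- floor(mm); hi <- ceiling(mm)
    if (lo == hi || hi > n) return(tp[min(lo, n)])
    tp[lo] + (mm - lo) * (tp[hi] - tp[lo])
  }
  vcc <- prob$voxel_cc
  oar_none <- list(
    urethra = d_hot(prob$organs$urethra$D, 0.1 / vcc),
    rectum = d_hot(prob$organs$rectum$D, 1 / vcc),
    bladder = d_hot(prob$organs$bladder$D, 1 / vcc))
  data.frame(
    scaling = s, preset = preset,
    V100 = m$V100, V150 = m$V150, V200 = m$V200,
    T10 = perc(10), T50 = perc(50), T90 = perc(90),
    Tmax = m$Tmax,
    urethra_D0.1cc = m$urethra_D0.1cc,
    rectum_D1cc = m$rectum_D1cc,
    bladder_D1cc = m$bladder_D1cc,
    urethra_D0.1cc_none = oar_none$urethra,
    rectum_D1cc_none = oar_none$rectum,
    bladder_D1cc_none = oar_none$bladder,
    feasible = opt$feasible, omega = opt$omega,
    stringsAsFactors = FALSE)
}
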