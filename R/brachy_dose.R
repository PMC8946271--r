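#' TG-43-style point-source model
#'
#' Point-source dose kernel `D(r) = strength * t * (r0/r)^2 * g(r) * phi_an`
#' with the radial dose function given as polynomial coefficients in `r`
#' (mm), normalized so `g(r0) = 1`, and a constant anisotropy factor.  With
#' the defaults (`g == 1`, `phi_an == 1`) the kernel is pure inverse square,
#' normalized so that a unit dwell weight delivers 1 Gy at the reference
#' distance.
#'
#' @param strength dose at `r0` per unit dwell weight (Gy).
#' @param r0 reference distance (mm).
#' @param radial_coef polynomial coefficients of g(r) (ascending powers of
#'   r in mm); rescaled internally so g(r0) = 1.
#' @param anisotropy constant anisotropy factor.
#' @return list of class `source_model`.
#' @export
source_model <- function(strength = 1, r0 = 10, radial_coef = 1,
                         anisotropy = 1) {
  g0 <- sum(radial_coef * r0^(seq_along(radial_coef) - 1))
  if (g0 <= 0) stop("radial dose function must be positive at r0")
  structure(list(strength = strength, r0 = r0,
                 radial_coef = radial_coef / g0, anisotropy = anisotropy),
            class = "source_model")
}

radial_g <- function(source, r) {
  g <- 0
  for (p in seq_along(source$radial_coef))
    g <- g + source$radial_coef[p] * r^(p - 1)
  g
}

#' Point-source dose rate at radial distances
#' @param source a [source_model()].
#' @param r radial distance (mm), vectorized.
#' @return dose per unit dwell weight (Gy).
#' @export
source_dose_at <- function(source, r) {
  source$strength * (source$r0 / r)^2 * radial_g(source, r) * source$anisotropy
}

#' Absorbed dose grid from dwell positions and weights
#'
#' Sums the point-source kernel over all dwells.  Radial distances are
#' capped from below at half the voxel diagonal so the dose stays bounded in
#' the source voxel.
#'
#' @param source a [source_model()].
#' @param dwells data.frame with columns `x`, `y`, `z` (world mm) and
#'   `weight` (>= 0; dwell time in kernel units).
#' @param grid a `voxel_grid` defining the output raster.
#' @return `voxel_grid` of absorbed dose (Gy).
#' @export
tg43_dose <- function(source, dwells, grid) {
  if (is.null(dwells) || nrow(dwells) == 0) stop("no dwells given")
  if (any(dwells$weight < 0)) stop("negative dwell weight")
  ax <- grid_axes(grid)
  inx <- range(ax$x); iny <- range(ax$y); inz <- range(ax$z)
  if (any(dwells$x < inx[1] | dwells$x > inx[2] |
          dwells$y < iny[1] | dwells$y > iny[2] |
          dwells$z < inz[1] | dwells$z > inz[2]))
    warning("dwell position outside grid; contribution still computed")
  rmin <- sqrt(sum(grid$spacing^2)) / 2
  D <- array(0, dim = grid$shape)
  dx2 <- outer(ax$x, dwells$x, "-")^2        # nx x ndwell
  dy2 <- outer(ax$y, dwells$y, "-")^2
  dz2 <- outer(ax$z, dwells$z, "-")^2
  for (d in seq_len(nrow(dwells))) {
    w <- dwells$weight[d]
    if (w == 0) next
    r2 <- outer(outer(dx2[, d], dy2[, d], "+"), dz2[, d], "+")
    r <- pmax(sqrt(r2), rmin)
    D <- D + w * source_dose_at(source, r)
  }
  grid_like(grid, D)
}

#' Clinical fraction-dose protocol
#'
#' Dose-volume objectives and constraints of the HDR-BT planning protocol,
#' relative to the prescription dose per fraction `Dp`.
#'
#' @param Dp prescription dose per fraction (Gy).
#' @return list with `Dp` and a criteria data.frame (organ, metric,
#'   threshold as fraction of Dp or volume %, direction, type).
#' @export
bt_protocol <- function(Dp = 13.5) {
  list(Dp = Dp, criteria = data.frame(
    organ  = c("prostate", "prostate", "prostate", "urethra", "rectum", "bladder"),
    metric = c("V100", "V150", "V200", "D0.1cc", "D1cc", "D1cc"),
    aim    = c(95, 30, 8, 1.15, 0.75, 0.75),
    # V* aims in % volume; D* aims as fraction of Dp
    dir    = c(">=", "<", "<", "<", "<", "<"),
    type   = c("objective", "soft", "soft", "hard", "hard", "soft"),
    stringsAsFactors = FALSE))
}

#' Heuristic brachytherapy plan for a phantom
#'
#' Surrogate for clinical inverse planning: fits nonnegative dwell weights
#' by nonnegative least squares to the prescription dose at sampled
#' prostate-surface points plus urethra-surface control points (which tame
#' the central dose the way a clinical urethra criterion would), then
#' rescales the plan uniformly so the prostate `V100 >= target_v100` holds
#' exactly at the order statistic.  Intended to produce protocol-compliant
#' BT-only plans on synthetic phantoms, not to replicate a clinical
#' optimizer; the report states which soft/hard criteria the surrogate
#' fails.
#'
#' @param model a `tbt_model` with candidate dwells.
#' @param source a [source_model()].
#' @param protocol a [bt_protocol()].
#' @param n_surface number of prostate-surface sample points.
#' @param n_urethra number of urethra-surface control points.
#' @param urethra_weight least-squares weight of the urethra points.
#' @param target_v100 coverage target (% of prostate volume).
#' @return list with `dwells` (weights filled in), `dose` (`voxel_grid`,
#'   Gy), `metrics` (achieved protocol metrics), `report` (criteria
#'   data.frame with achieved values and pass flags).
#' @export
heuristic_dwell_weights <- function(model, source = source_model(),
                                    protocol = bt_protocol(),
                                    n_surface = 400, n_urethra = 120,
                                    urethra_weight = 3, target_v100 = 95) {
  dw <- model$dwells
  if (is.null(dw) || nrow(dw) == 0)
    stop("infeasible geometry: no candidate dwell positions in target")
  semi <- model$semiaxes
  # Fibonacci-sphere surface sampling of the prostate ellipsoid
  i <- seq_len(n_surface)
  phi <- acos(1 - 2 * (i - 0.5) / n_surface)
  theta <- pi * (1 + sqrt(5)) * i
  pts_s <- cbind(semi[1] * sin(phi) * cos(theta),
                 semi[2] * sin(phi) * sin(theta),
                 semi[3] * cos(phi))
  # urethra cylinder surface, evenly wound over the prostatic length
  j <- seq_len(n_urethra)
  ru <- model$config$urethra_radius
  thu <- 2 * pi * (1 + sqrt(5)) * j
  zu <- semi[3] * 0.8 * (2 * (j - 0.5) / n_urethra - 1)
  pts_u <- cbind(ru * cos(thu), ru * sin(thu), zu)

  kernel_at <- function(pts) {
    A <- matrix(0, nrow(pts), nrow(dw))
    for (d in seq_len(nrow(dw))) {
      r <- sqrt((pts[, 1] - dw$x[d])^2 + (pts[, 2] - dw$y[d])^2 +
                  (pts[, 3] - dw$z[d])^2)
      A[, d] <- source_dose_at(source, pmax(r, 0.5))
    }
    A
  }
  A <- rbind(kernel_at(pts_s), urethra_weight * kernel_at(pts_u))
  b <- c(rep(protocol$Dp, n_surface),
         urethra_weight * rep(protocol$Dp, n_urethra))
  fit <- pracma::lsqnonneg(A, b)
  dw$weight <- fit$x
  if (all(dw$weight == 0))
    stop("infeasible geometry: all dwell weights zero")

  D <- tg43_dose(source, dw, model$grid)
  pmask <- organ_mask(model, "prostate")
  # uniform rescale: the dose of the voxel at the target coverage order
  # statistic becomes exactly Dp, so V100 (>= convention) >= target
  ds <- sort(D$values[pmask], decreasing = TRUE)
  # the 1e-9 guard keeps the order-statistic voxel on the covered side of
  # the >= threshold under floating-point rounding
  s <- (1 + 1e-9) * protocol$Dp / ds[ceiling(target_v100 / 100 * length(ds))]
  dw$weight <- dw$weight * s
  D <- grid_like(D, D$values * s)

  report <- bt_plan_report(D, model, protocol)
  list(dwells = dw, dose = D, metrics = report$metrics, report = report$table)
}

bt_plan_report <- function(D, model, protocol) {
  vcc <- voxel_cc(D)
  pmask <- organ_mask(model, "prostate")
  m <- list(
    V100 = volume_fraction_at(D$values, pmask, protocol$Dp),
    V150 = volume_fraction_at(D$values, pmask, 1.5 * protocol$Dp),
    V200 = volume_fraction_at(D$values, pmask, 2.0 * protocol$Dp),
    urethra_D0.1cc = dose_at_volume_cc(D$values, organ_mask(model, "urethra"),
                                       0.1, vcc),
    rectum_D1cc = dose_at_volume_cc(D$values, organ_mask(model, "rectum"),
                                    1, vcc),
    bladder_D1cc = dose_at_volume_cc(D$values, organ_mask(model, "bladder"),
                                     1, vcc))
  cr <- protocol$criteria
  ach <- c(m$V100, m$V150, m$V200,
           m$urethra_D0.1cc / protocol$Dp,
           m$rectum_D1cc / protocol$Dp,
           m$bladder_D1cc / protocol$Dp)
  pass <- ifelse(cr$dir == ">=", ach >= cr$aim, ach < cr$aim)
  cr$achieved <- ach
  cr$pass <- pass
  list(metrics = m, table = cr)
}

#' Uniformly scale a dose grid
#'
#' @param D dose `voxel_grid` (Gy).
#' @param s positive scale factor (fraction of the original plan; values
#'   above 1 are permitted for escalation studies).
#' @return scaled `voxel_grid` with a `dose_scaling` attribute recording the
#'   cumulative scaling relative to the original plan.
#' @export
scale_dose <- function(D, s) {
  if (s <= 0) stop("validation error: dose scaling must be > 0")
  prev <- attr(D, "dose_scaling")
  out <- grid_like(D, D$values * s)
  attr(out, "dose_scaling") <- s * (if (is.null(prev)) 1 else prev)
  out
}
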