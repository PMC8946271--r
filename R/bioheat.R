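#' Low-level steady-state temperature-elevation solve
#'
#' Solves `-div(k grad dT) + s dT = P` with Dirichlet voxels held at fixed
#' elevations, where `s = rho_b c_b rho omega` is the Pennes perfusion sink
#' coefficient (W/m^3/K).  This is the elevation form of the steady-state
#' Pennes bioheat equation about the baseline `Tb`.
#'
#' @param grid a `voxel_grid` (raster only).
#' @param k thermal conductivity array (W/m/K).
#' @param sink perfusion sink coefficient array (W/m^3/K), `>= 0`.
#' @param P volumetric power density array (W/m^3), `>= 0`.
#' @param dirichlet logical array, TRUE where elevation is fixed.
#' @param fixed fixed elevation values (K) at Dirichlet voxels.
#' @param tol,maxit solver settings.
#' @return `voxel_grid` of temperature elevation (K), with `iterations` and
#'   `relative_residual` attributes.
#' @export
solve_elevation <- function(grid, k, sink, P, dirichlet,
                            fixed = array(0, dim = grid$shape),
                            tol = 1e-8, maxit = 20000L) {
  if (any(k < 0) || any(sink < 0)) stop("validation error: negative property")
  res <- .stencil_solve_cpp(
    dims = grid$shape, spacing_m = grid$spacing * 1e-3,
    a_cell = as.complex(k), sink_cell = as.numeric(sink),
    src_cell = as.complex(P), dirichlet = as.integer(dirichlet),
    u_fixed = as.complex(fixed), tol = tol, maxit = as.integer(maxit))
  if (!res$converged)
    stop(sprintf("solver error: bioheat solve did not converge (relative residual %.3g after %d iterations)",
                 res$relative_residual, res$iterations))
  out <- grid_like(grid, array(Re(res$u), dim = grid$shape))
  attr(out, "iterations") <- res$iterations
  attr(out, "relative_residual") <- res$relative_residual
  out
}

#' Steady-state Pennes bioheat solve for a power deposition
#'
#' Solves for the steady temperature elevation above the 37 degree C baseline
#' with Dirichlet baseline temperature on the domain boundary.  Internal air
#' voxels are excluded from the conduction stencil (insulating faces, held at
#' baseline), so no heat is conducted through e.g. the rectal lumen.
#'
#' @param model a `tbt_model`.
#' @param P power density array (W/m^3) over the model grid.
#' @param props optional [property_grids()].
#' @param tol,maxit solver settings.
#' @return `voxel_grid` of absolute temperature (degrees C).
#' @export
solve_bioheat <- function(model, P, props = property_grids(model),
                          tol = 1e-8, maxit = 20000L) {
  if (any(P < 0)) stop("validation error: negative power density")
  grid <- model$grid
  air <- model$grid$values == model$labels[["air"]]
  k <- props$k
  k[air] <- 0  # harmonic-mean faces to air become insulating
  sink <- model$blood$rho_b * model$blood$c_b * props$rho * props$omega_si
  dirichlet <- boundary_mask(grid$shape) | air
  dT <- solve_elevation(grid, k, sink, P, dirichlet, tol = tol, maxit = maxit)
  out <- grid_like(grid, dT$values + model$blood$Tb)
  attr(out, "iterations") <- attr(dT, "iterations")
  attr(out, "relative_residual") <- attr(dT, "relative_residual")
  out
}

#' Precompute unit-amplitude temperature elevations per electrode
#'
#' One steady-state bioheat solve per electrode at unit drive amplitude.
#' These elevation fields are reused by every optimizer evaluation through
#' [superpose_temperature()].
#'
#' @param model a `tbt_model`.
#' @param unit_powers list of per-electrode power density arrays (W/m^3)
#'   from [unit_power_per_electrode()].
#' @param props optional [property_grids()].
#' @param tol,maxit solver settings.
#' @param verbose print progress.
#' @return list of elevation arrays (K), one per electrode.
#' @export
precompute_delta_t <- function(model, unit_powers,
                               props = property_grids(model),
                               tol = 1e-8, maxit = 20000L, verbose = FALSE) {
  out <- vector("list", length(unit_powers))
  names(out) <- names(unit_powers)
  for (i in seq_along(unit_powers)) {
    if (verbose) message(sprintf("bioheat solve %d/%d", i, length(unit_powers)))
    Ti <- tryCatch(
      solve_bioheat(model, unit_powers[[i]], props, tol = tol, maxit = maxit),
      error = function(e) stop(sprintf("electrode %d: %s", i, conditionMessage(e))))
    out[[i]] <- Ti$values - model$blood$Tb
  }
  out
}

#' Temperature by per-electrode superposition
#'
#' `T = Tb + sum_i v_i^2 dT_i`: the quadratic amplitude dependence of the
#' power makes unit-amplitude elevations superpose with squared amplitudes
#' once the interference (cross) terms between electrodes are neglected.
#'
#' @param delta_t list of per-electrode elevation arrays (K).
#' @param v amplitude vector (real, nonnegative).
#' @param Tb baseline temperature (degrees C).
#' @return temperature array (degrees C).
#' @export
superpose_temperature <- function(delta_t, v, Tb = 37) {
  if (length(delta_t) != length(v))
    stop("dimension error: basis and amplitude vector lengths differ")
  acc <- array(Tb, dim = dim(delta_t[[1]]))
  for (i in seq_along(delta_t)) acc <- acc + v[i]^2 * delta_t[[i]]
  acc
}

#' Coupled reference temperature recalculation
#'
#' Builds the total power density including all electrode cross terms from
#' the E-field basis and performs a single coupled bioheat solve.  This is
#' the validation reference against which the superposition approximation is
#' scored with the 3D gamma index.
#'
#' @param model a `tbt_model`.
#' @param efields list of per-electrode E-fields ([efield()] output).
#' @param v amplitude vector.
#' @param props optional [property_grids()].
#' @param tol,maxit solver settings.
#' @return temperature `voxel_grid` (degrees C).
#' @export
reference_recalculation <- function(model, efields, v,
                                    props = property_grids(model),
                                    tol = 1e-8, maxit = 20000L) {
  P <- power_density(efields, v, props$sigma)
  solve_bioheat(model, P, props, tol = tol, maxit = maxit)
}
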