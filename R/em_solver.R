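#' @useDynLib tbtplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Low-level electroquasistatic solve on a voxel grid
#'
#' Solves the flux-conservative finite-difference discretization of
#' `div((sigma + j 2 pi f eps) grad V) = 0` with arbitrary Dirichlet voxels,
#' using harmonic-mean face admittances and a Jacobi-preconditioned conjugate
#' orthogonal CG iteration (plain PCG in the real limit).
#'
#' @param grid a `voxel_grid` (raster only; values ignored).
#' @param admittance complex array over the grid, `sigma + 1i * 2 pi f eps`
#'   (S/m).
#' @param dirichlet logical array, TRUE where the potential is fixed.
#' @param fixed numeric/complex array of fixed potential values (volts);
#'   entries outside `dirichlet` are ignored.
#' @param tol relative residual tolerance.
#' @param maxit maximum iterations.
#' @return a `voxel_grid` of complex potential (V) with attributes
#'   `iterations` and `relative_residual`.
#' @export
solve_quasistatic <- function(grid, admittance, dirichlet, fixed,
                              tol = 1e-8, maxit = 20000L) {
  if (!any(dirichlet)) stop("setup error: no Dirichlet voxels")
  res <- .stencil_solve_cpp(
    dims = grid$shape, spacing_m = grid$spacing * 1e-3,
    a_cell = as.complex(admittance),
    sink_cell = numeric(length(admittance)),
    src_cell = complex(length(admittance)),
    dirichlet = as.integer(dirichlet),
    u_fixed = as.complex(fixed),
    tol = tol, maxit = as.integer(maxit))
  if (!res$converged)
    stop(sprintf("solver error: quasistatic solve did not converge (relative residual %.3g after %d iterations)",
                 res$relative_residual, res$iterations))
  out <- grid_like(grid, array(res$u, dim = grid$shape))
  attr(out, "iterations") <- res$iterations
  attr(out, "relative_residual") <- res$relative_residual
  out
}

#' Complex admittance grid at the model operating frequency
#' @param model a `tbt_model`.
#' @param props optional precomputed [property_grids()].
#' @return complex array, `sigma + j 2 pi f eps0 eps_r` (S/m).
#' @export
admittance_grid <- function(model, props = property_grids(model)) {
  props$sigma + 1i * 2 * pi * model$frequency * EPS0 * props$eps_r
}

#' Thin-coating effective admittance for electrode voxels
#'
#' The Parylene coating is orders of magnitude thinner than a voxel, so it
#' is modelled as a sheet admittance in series with each electrode-tissue
#' face rather than as resolved voxels.  With harmonic-mean face averaging,
#' assigning the electrode cell the effective coefficient
#' `a_eff = (h/2) (sigma_c + j w eps0 epsr_c) / t_c` reproduces exactly the
#' series combination of the half-cell of tissue and a coating layer of
#' thickness `t_c` (`h` = cell size).
#'
#' @param model a `tbt_model` (frequency and dielectric properties).
#' @param thickness_mm coating thickness (mm).
#' @return complex scalar, effective cell admittance (S/m).
#' @export
coating_admittance <- function(model, thickness_mm) {
  die <- model$properties[model$properties$tissue == "dielectric", ]
  h <- mean(model$grid$spacing) * 1e-3
  y_per_area <- (die$sigma + 1i * 2 * pi * model$frequency * EPS0 * die$eps_r) /
    (thickness_mm * 1e-3)
  (h / 2) * y_per_area
}

#' Solve the per-electrode potential
#'
#' Dirichlet conditions: the active electrode's voxels at `drive` volts, all
#' other electrode voxels grounded (0 V), and the outer domain boundary at
#' 0 V.  Grounding the inactive electrodes makes the per-electrode solutions
#' an exact linear basis for amplitude superposition (a channel driven at
#' zero amplitude is a short to ground, so the inactive state is the zero
#' amplitude).  Electrode voxels carry the thin-coating effective admittance
#' of [coating_admittance()] when the applicator has a nonzero coating
#' thickness, which capacitively decouples the electrodes from the tissue
#' and from each other as in the physical applicator.
#'
#' @param model a `tbt_model`.
#' @param electrode_index which electrode (in [electrode_table()] order).
#' @param ras electrode rasterization from [rasterize_electrodes()]
#'   (recomputed if NULL).
#' @param props optional [property_grids()].
#' @param drive Dirichlet potential of the active electrode (V).
#' @param tol,maxit solver settings.
#' @return complex potential `voxel_grid` (V).
#' @export
solve_potential <- function(model, electrode_index,
                            ras = NULL, props = NULL,
                            drive = 1, tol = 1e-8, maxit = 20000L) {
  if (is.null(ras)) ras <- rasterize_electrodes(model)
  if (is.null(props)) props <- property_grids(model)
  if (electrode_index < 1 || electrode_index > length(ras))
    stop("electrode_index out of range")
  grid <- model$grid
  adm <- admittance_grid(model, props)
  thick <- electrode_coating_mm(model)
  for (i in seq_along(ras))
    if (thick[i] > 0) adm[ras[[i]]] <- coating_admittance(model, thick[i])
  dirichlet <- boundary_mask(grid$shape)
  for (v in ras) dirichlet[v] <- TRUE
  fixed <- array(0, dim = grid$shape)
  fixed[ras[[electrode_index]]] <- drive
  solve_quasistatic(grid, adm, dirichlet, fixed, tol = tol, maxit = maxit)
}

# per-electrode coating thickness (mm), in electrode_table order
electrode_coating_mm <- function(model) {
  unlist(lapply(model$applicators, function(a)
    rep(a$coating_thickness, nrow(a$electrodes))))
}

#' Electric field from a potential field
#'
#' `E = -grad V`, central differences in the interior and one-sided at the
#' grid faces; spacing in mm is converted so E is in V/m.
#'
#' @param V potential `voxel_grid` (V).
#' @return list of three arrays `Ex`, `Ey`, `Ez` (V/m, complex if V is).
#' @export
efield <- function(V) {
  h <- V$spacing * 1e-3
  list(Ex = -grad_axis(V$values, 1, h[1]),
       Ey = -grad_axis(V$values, 2, h[2]),
       Ez = -grad_axis(V$values, 3, h[3]))
}

grad_axis <- function(a, axis, h) {
  n <- dim(a)[axis]
  if (n < 2) return(array(0, dim = dim(a)))
  idx <- function(r) {
    ix <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    ix[[axis]] <- r
    do.call(`[`, c(list(a), ix, list(drop = FALSE)))
  }
  fwd <- idx(c(2:n, n))
  bwd <- idx(c(1, 1:(n - 1)))
  denom <- rep(2 * h, n)
  denom[c(1, n)] <- h
  dd <- array(1, dim = dim(a))
  per <- rep(denom, each = prod(dim(a)[seq_len(axis - 1)]))
  dd[] <- per  # recycles along the remaining axes
  (fwd - bwd) / dd
}

#' Power loss density of an amplitude-weighted field combination
#'
#' Coherent superposition including all cross terms:
#' `E_tot = sum_i v_i E_i`, `P = sigma |E_tot|^2 / 2` (W/m^3).
#'
#' @param basis list of E-fields (each a list `Ex`,`Ey`,`Ez` as returned by
#'   [efield()]).
#' @param v amplitude vector (length = number of basis fields).
#' @param sigma conductivity array (S/m).
#' @return real array, power loss density (W/m^3).
#' @export
power_density <- function(basis, v, sigma) {
  if (length(basis) != length(v))
    stop("dimension error: basis and amplitude vector lengths differ")
  dims <- dim(basis[[1]]$Ex)
  Ex <- array(0i, dims); Ey <- array(0i, dims); Ez <- array(0i, dims)
  for (i in seq_along(basis)) {
    Ex <- Ex + v[i] * basis[[i]]$Ex
    Ey <- Ey + v[i] * basis[[i]]$Ey
    Ez <- Ez + v[i] * basis[[i]]$Ez
  }
  sigma / 2 * (Mod(Ex)^2 + Mod(Ey)^2 + Mod(Ez)^2)
}

#' Unit-amplitude power density per electrode
#'
#' Diagonal terms of the power quadratic form: `P_i = sigma |E_i|^2 / 2`.
#'
#' @inheritParams power_density
#' @return list of real arrays, one per electrode (W/m^3).
#' @export
unit_power_per_electrode <- function(basis, sigma) {
  lapply(basis, function(E)
    sigma / 2 * (Mod(E$Ex)^2 + Mod(E$Ey)^2 + Mod(E$Ez)^2))
}
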