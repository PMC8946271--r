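#' Temperature-dependent linear-quadratic parameter set
#'
#' Radiosensitization parameters of the TDLQ model: the LQ alpha/beta ratio
#' at 37 degrees C and the fold-changes of alpha and beta at a reference
#' temperature `Tref`.  Between 37 and `Tref` the fold-change interpolates
#' exponentially (see [thermal_ratio()]); beyond `Tref` the same law
#' extrapolates.
#'
#' @param alpha_ratio alpha(Tref)/alpha(37), > 0.
#' @param beta_ratio beta(Tref)/beta(37), > 0.
#' @param alpha_beta_37 alpha/beta ratio at 37 C (Gy), > 0.
#' @param Tref reference temperature (degrees C), > 37.
#' @param G Lea-Catcheside dose protraction factor (1 for HDR exposure).
#' @param name optional preset name.
#' @return object of class `tdlq_params`.
#' @export
tdlq_params <- function(alpha_ratio, beta_ratio, alpha_beta_37 = 3,
                        Tref = 43, G = 1, name = NULL) {
  if (alpha_beta_37 <= 0) stop("alpha_beta_37 must be > 0")
  if (alpha_ratio <= 0 || beta_ratio <= 0) stop("ratios must be > 0")
  if (Tref <= 37) stop("Tref must exceed 37 C")
  structure(list(alpha_ratio = alpha_ratio, beta_ratio = beta_ratio,
                 alpha_beta_37 = alpha_beta_37, Tref = Tref, G = G,
                 name = name),
            class = "tdlq_params")
}

#' Bundled thermoradiobiological presets
#'
#' In vitro prostate cancer cell-line parameter sets at `Tref` = 43 C:
#' `PC3` (alpha ratio 2.4, beta ratio 6.8), `DU145` (0.8, 1.8), their
#' arithmetic mean `AVG` (1.6, 4.3), and `NONE` (1, 1), the
#' no-sensitization setting under which the equivalent dose equals the
#' physical dose at every temperature.
#'
#' @param name one of "PC3", "DU145", "AVG", "NONE".
#' @param alpha_beta_37 alpha/beta at 37 C (Gy).
#' @return a [tdlq_params()] object.
#' @export
tdlq_preset <- function(name = c("PC3", "DU145", "AVG", "NONE"),
                        alpha_beta_37 = 3) {
  name <- match.arg(name)
  r <- switch(name,
              PC3   = c(2.4, 6.8),
              DU145 = c(0.8, 1.8),
              AVG   = c(1.6, 4.3),
              NONE  = c(1.0, 1.0))
  tdlq_params(r[1], r[2], alpha_beta_37 = alpha_beta_37, name = name)
}

#' Average of two TDLQ parameter sets
#'
#' Arithmetic mean of the alpha and beta fold-changes; used to form the
#' average prostate preset from the PC-3 and DU-145 cell-line data.
#'
#' @param a,b [tdlq_params()] objects with identical `Tref` and
#'   `alpha_beta_37`.
#' @return a [tdlq_params()] object.
#' @export
average_params <- function(a, b) {
  if (a$Tref != b$Tref || a$alpha_beta_37 != b$alpha_beta_37)
    stop("validation error: parameter sets differ in Tref or alpha/beta")
  tdlq_params((a$alpha_ratio + b$alpha_ratio) / 2,
              (a$beta_ratio + b$beta_ratio) / 2,
              alpha_beta_37 = a$alpha_beta_37, Tref = a$Tref, G = a$G,
              name = "mean")
}

#' Exponential thermal fold-change
#'
#' `exp((T - 37)/(Tref - 37) * log(ratio))`: equals 1 at 37 C and
#' `ratio_at_Tref` at `Tref`; the same law extrapolates outside `[37, Tref]`.
#'
#' @param T temperature (degrees C), vectorized.
#' @param ratio_at_Tref fold-change at the reference temperature, > 0.
#' @param Tref reference temperature (degrees C).
#' @return dimensionless factor, same shape as `T`.
#' @export
thermal_ratio <- function(T, ratio_at_Tref, Tref = 43) {
  if (ratio_at_Tref <= 0) stop("domain error: ratio must be > 0")
  exp((T - 37) / (Tref - 37) * log(ratio_at_Tref))
}

#' TDLQ cell survival
#'
#' `S(D, T) = exp(-alpha(T) D - beta(T) D^2)` for a 1 h simultaneous
#' exposure, with `alpha(T)`, `beta(T)` scaled from their 37 C values by
#' [thermal_ratio()].  Absolute `alpha37`/`beta37` must be supplied; the
#' planning pipeline itself only needs the equivalent dose, which depends on
#' their ratio alone.
#'
#' @param D radiation dose (Gy), >= 0, vectorized.
#' @param T temperature (degrees C), vectorized.
#' @param alpha37 LQ alpha at 37 C (1/Gy).
#' @param beta37 LQ beta at 37 C (1/Gy^2).
#' @param params a [tdlq_params()] (only the ratios and Tref are used).
#' @return surviving fraction in (0, 1].
#' @export
survival_fraction <- function(D, T, alpha37, beta37, params) {
  if (any(D < 0)) stop("domain error: negative dose")
  ra <- thermal_ratio(T, params$alpha_ratio, params$Tref)
  rb <- thermal_ratio(T, params$beta_ratio, params$Tref)
  exp(-alpha37 * ra * D - beta37 * rb * params$G * D^2)
}

#' Equivalent physical dose of a combined radiation/heat exposure
#'
#' The radiation-only dose that would produce the same LQ cell kill as dose
#' `D` delivered at temperature `T`, normalized to the physical dose:
#' `EQD_phys = (ab * ra(T) * D + rb(T) * D^2) / (ab + D)` with
#' `ab = alpha/beta at 37 C` and `ra`, `rb` from [thermal_ratio()].  At 37 C
#' (or with the `NONE` preset) this collapses to `D` exactly.
#'
#' @param D dose (Gy), vectorized.
#' @param T temperature (degrees C), vectorized (recycled against `D`).
#' @param params a [tdlq_params()].
#' @return equivalent physical dose (Gy), same shape as `D`.
#' @export
eqd_phys <- function(D, T, params) {
  if (any(D < 0)) stop("domain error: negative dose")
  ab <- params$alpha_beta_37
  ra <- thermal_ratio(T, params$alpha_ratio, params$Tref)
  rb <- thermal_ratio(T, params$beta_ratio, params$Tref)
  (ab * ra * D + rb * D^2) / (ab + D)
}

#' Equivalent physical dose grid with per-tissue parameters
#'
#' Applies [eqd_phys()] voxel-wise with tissue-specific TDLQ parameter sets.
#' Voxels whose tissue is not listed keep their physical dose (equivalent to
#' the `NONE` preset).
#'
#' @param D dose `voxel_grid` (Gy).
#' @param T temperature `voxel_grid` or array (degrees C).
#' @param model a `tbt_model` providing the label grid.
#' @param tissue_params named list mapping tissue name to [tdlq_params()].
#' @return `voxel_grid` of EQD_phys (Gy).
#' @export
eqd_phys_grid <- function(D, T, model, tissue_params) {
  Tv <- if (inherits(T, "voxel_grid")) {
    stopifnot_same_raster(D, T)
    T$values
  } else {
    if (!identical(dim(T), dim(D$values)))
      stop("dimension error: dose and temperature rasters differ")
    T
  }
  out <- D$values
  lab <- model$grid$values
  for (tissue in names(tissue_params)) {
    sel <- lab == model$labels[[tissue]]
    if (!any(sel)) next
    out[sel] <- eqd_phys(D$values[sel], Tv[sel], tissue_params[[tissue]])
  }
  grid_like(D, out)
}

#' Tabulate equivalent dose over a dose/temperature lattice
#'
#' Long-format table of `EQD_phys` over a (D, T) grid, convenient for
#' exporting as CSV and drawing equal-kill isodose curves.
#'
#' @param D dose grid values (Gy).
#' @param T temperature grid values (degrees C).
#' @param params a [tdlq_params()].
#' @return data.frame with columns `D`, `T`, `eqd`.
#' @export
eqd_table <- function(D = seq(0, 20, by = 0.25),
                      T = seq(37, 47.5, by = 0.25), params) {
  g <- expand.grid(D = D, T = T)
  g$eqd <- eqd_phys(g$D, g$T, params)
  g
}

#' Per-tissue TDLQ assignment for a planning run
#'
#' Builds the tissue -> parameter map used by [eqd_phys_grid()]: the tumor
#' preset for the prostate, and for every normal tissue (urethra, rectum,
#' bladder, muscle, fat, bone) either the same preset (`"worst"` case, equal
#' normal-tissue sensitization) or `NONE` (`"none"`, no normal-tissue
#' sensitization).
#'
#' @param tumor a [tdlq_params()] for the target.
#' @param oar_mode `"worst"` or `"none"`.
#' @return named list of [tdlq_params()].
#' @export
tissue_param_map <- function(tumor, oar_mode = c("worst", "none")) {
  oar_mode <- match.arg(oar_mode)
  oar <- if (oar_mode == "worst") tumor else
    tdlq_preset("NONE", alpha_beta_37 = tumor$alpha_beta_37)
  list(prostate = tumor, urethra = oar, rectum = oar, bladder = oar,
       muscle = oar, fat = oar, bone = oar)
}
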