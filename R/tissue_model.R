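#' Tissue label enumeration
#'
#' Named integer codes used in label grids.  `muscle` is the background
#' tissue; `dielectric` is the applicator coating material (only present when
#' coating voxels are explicitly modelled).
#' @export
tissue_labels <- c(muscle = 1L, fat = 2L, bone = 3L, prostate = 4L,
                   urethra = 5L, rectum = 6L, bladder = 7L, air = 8L,
                   dielectric = 9L)

#' Electric and thermal tissue properties
#'
#' Bundled per-tissue property table: mass density `rho` (kg/m^3), electrical
#' conductivity `sigma` at 27 MHz (S/m), relative permittivity `eps_r` at
#' 27 MHz, specific heat `c` (J/kg/K), thermal conductivity `k` (W/m/K) and
#' blood perfusion `omega` (ml/kg/min; 0 for non-perfused materials).
#'
#' @return data.frame with one row per tissue/material.
#' @export
tissue_table <- function() {
  data.frame(
    tissue = c("dielectric", "air", "muscle", "fat", "bone",
               "prostate", "rectum", "urethra", "bladder"),
    rho    = c(1289, 1.164, 1090.4, 911, 1908, 1045, 1045, 1102, 1086),
    sigma  = c(1e-5, 0, 0.654, 0.061, 0.052, 0.838, 0.654, 0.375, 0.276),
    eps_r  = c(2.4, 1.0, 95.8, 17.9, 21.8, 120.1, 95.8, 88.8, 31.5),
    c      = c(712, 1004, 3421, 2348, 1313, 3760, 3801, 3306, 3581),
    k      = c(0.084, 0.0273, 0.495, 0.211, 0.320, 0.512, 0.557, 0.462, 0.522),
    omega  = c(0, 0, 40, 33, 10, 394, 0, 394, 78),
    stringsAsFactors = FALSE
  )
}

#' Blood properties for the Pennes perfusion term
#'
#' @param Tb arterial/baseline temperature (degrees C).
#' @param rho_b blood mass density (kg/m^3).
#' @param c_b blood specific heat (J/kg/K).
#' @return list of class `blood_properties`.
#' @export
blood_properties <- function(Tb = 37, rho_b = 1050, c_b = 3617) {
  if (rho_b <= 0 || c_b <= 0) stop("blood density and specific heat must be > 0")
  structure(list(Tb = Tb, rho_b = rho_b, c_b = c_b),
            class = "blood_properties")
}

#' Convert perfusion from ml/kg/min to SI volumetric perfusion
#'
#' @param omega_ml perfusion in ml blood per kg tissue per minute.
#' @return perfusion in m^3 blood per kg tissue per second.
#' @export
perfusion_si <- function(omega_ml) omega_ml * 1e-6 / 60

#' Dual-function applicator geometry
#'
#' A straight implant track carrying two cylindrical electrodes (distal and
#' proximal) defined by arc-length intervals along the track.
#'
#' @param id identifier string.
#' @param p0,p1 numeric length-3 world points (mm), the track end points
#'   (`p0` = entry/inferior end).
#' @param electrodes data.frame with columns `s_start`, `s_end` (mm arc
#'   length from `p0`), one row per electrode, ordered proximal to distal.
#' @param radius catheter/electrode radius (mm).
#' @param coating_thickness dielectric coating thickness (mm); 0 means the
#'   coating is not resolved on the grid.
#' @return list of class `applicator`.
#' @export
applicator <- function(id, p0, p1, electrodes, radius = 1,
                       coating_thickness = 0) {
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("applicator track has zero length")
  if (any(electrodes$s_start < 0) || any(electrodes$s_end > len))
    stop("electrode segment outside applicator track")
  if (any(electrodes$s_end <= electrodes$s_start))
    stop("electrode segment has non-positive length")
  o <- order(electrodes$s_start)
  e <- electrodes[o, , drop = FALSE]
  if (nrow(e) > 1 && any(e$s_start[-1] < e$s_end[-nrow(e)]))
    stop("electrode segments overlap")
  structure(list(id = id, p0 = as.numeric(p0), p1 = as.numeric(p1),
                 length = len, electrodes = e, radius = radius,
                 coating_thickness = coating_thickness),
            class = "applicator")
}

applicator_point <- function(app, s) {
  u <- (app$p1 - app$p0) / app$length
  sweep(outer(s, u), 2, app$p0, "+")
}

#' Flat table of electrodes across all applicators
#'
#' @param model a `tbt_model`.
#' @return data.frame with applicator id, electrode name, segment end points
#'   (world mm) and radius; one row per electrode, in solver order.
#' @export
electrode_table <- function(model) {
  rows <- lapply(model$applicators, function(app) {
    segs <- app$electrodes
    pts0 <- applicator_point(app, segs$s_start)
    pts1 <- applicator_point(app, segs$s_end)
    data.frame(applicator = app$id,
               electrode = paste0(app$id, ".", seq_len(nrow(segs))),
               x0 = pts0[, 1], y0 = pts0[, 2], z0 = pts0[, 3],
               x1 = pts1[, 1], y1 = pts1[, 2], z1 = pts1[, 3],
               radius = app$radius, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default synthetic pelvic phantom configuration
#'
#' Parameters of [generate_phantom()].  The defaults describe a 96 mm cube at
#' 1.5 mm isotropic resolution holding a ~35 cc ellipsoidal prostate with a
#' coaxial urethra, a posterior air-filled rectum, a superior bladder and a
#' fat/muscle background, implanted with 18 dual-electrode applicators placed
#' on a 5 mm perineal template grid with seeded jitter.
#'
#' @param shape,spacing grid geometry (voxels, mm).
#' @param n_applicators number of implanted applicators.
#' @param template_spacing template grid pitch (mm).
#' @param jitter_sd standard deviation of transverse placement jitter (mm).
#' @param prostate_semiaxes ellipsoid semi-axes (mm, x/y/z).
#' @param prostate_jitter relative jitter on semi-axes (fraction).
#' @param urethra_radius urethra cylinder radius (mm).
#' @param rectum_radius,rectum_air_radius rectum outer wall and air-lumen
#'   radii (mm).
#' @param rectum_gap tissue gap between prostate surface and rectal wall (mm).
#' @param bladder_radius bladder sphere radius (mm).
#' @param fat_radius radial distance beyond which background is fat (mm).
#' @param electrode_length,electrode_gap electrode segment length and
#'   inter-electrode gap (mm).
#' @param catheter_radius applicator radius (mm).
#' @param coating_thickness Parylene coating thickness (mm); modelled as a
#'   thin-sheet series admittance on the electrode surface.
#' @param applicator_margin minimum distance of a track from the prostate
#'   surface in the template plane (mm).
#' @param urethra_margin minimum distance of a track from the urethra axis (mm).
#' @param dwell_step dwell-position spacing along a track (mm).
#' @param dwell_margin margin from the prostate surface for dwell activation (mm).
#' @param frequency operating frequency of the CC-RF heating (Hz).
#' @return named list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
                           n_applicators = 18, template_spacing = 5,
                           jitter_sd = 0.5,
                           prostate_semiaxes = c(22.5, 19, 19.5),
                           prostate_jitter = 0.03,
                           urethra_radius = 3,
                           rectum_radius = 10, rectum_air_radius = 6,
                           rectum_gap = 4,
                           bladder_radius = 15,
                           fat_radius = 42,
                           electrode_length = 20, electrode_gap = 5,
                           catheter_radius = 1, coating_thickness = 0.02,
                           applicator_margin = 3, urethra_margin = 6,
                           dwell_step = 2.5, dwell_margin = 2,
                           frequency = 27e6) {
  cfg <- as.list(environment())
  structure(cfg, class = "phantom_config")
}

#' Generate a synthetic pelvic phantom with implanted applicators
#'
#' Builds a voxel tissue model emulating the anatomy and implant geometry of
#' a prostate ThermoBrachyTherapy patient: ellipsoidal prostate with coaxial
#' urethra, posterior rectum with air lumen, superior bladder, fat/muscle
#' background, and `n_applicators` straight applicators (two 20 mm electrodes
#' with a 5 mm gap each) on a template grid with seeded jitter.  The output
#' is deterministic for a fixed `(config, seed)` pair.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed controlling jitter and template selection.
#' @return a `tbt_model`: list with `grid` (label `voxel_grid`), `properties`
#'   (tissue table), `blood`, `applicators`, `frequency`, `dwells` (candidate
#'   dwell positions), `config`, `seed`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1) {
  cfg <- config
  if (max(cfg$spacing) >= cfg$electrode_gap)
    stop("configuration error: grid spacing must resolve the electrode gap")
  grid <- voxel_grid(cfg$shape, cfg$spacing)
  ax <- grid_axes(grid)

  with_seed(seed, {
    semi <- cfg$prostate_semiaxes *
      (1 + stats::runif(3, -cfg$prostate_jitter, cfg$prostate_jitter))

    X <- array(ax$x, dim = cfg$shape)
    Y <- aperm(array(ax$y, dim = cfg$shape[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(ax$z, dim = cfg$shape[c(3, 2, 1)]), c(3, 2, 1))

    lab <- array(tissue_labels[["muscle"]], dim = cfg$shape)
    r_xy2 <- X^2 + Y^2
    lab[r_xy2 > cfg$fat_radius^2] <- tissue_labels[["fat"]]

    # bladder: sphere superior-anterior of the prostate
    bl_c <- c(0, 6, semi[3] + 13)
    bl <- (X - bl_c[1])^2 + (Y - bl_c[2])^2 + (Z - bl_c[3])^2 <=
      cfg$bladder_radius^2
    lab[bl] <- tissue_labels[["bladder"]]

    # rectum: posterior cylinder along z with an air lumen
    rect_y <- -(semi[2] + cfg$rectum_gap + cfg$rectum_radius)
    r_rect2 <- X^2 + (Y - rect_y)^2
    lab[r_rect2 <= cfg$rectum_radius^2] <- tissue_labels[["rectum"]]
    lab[r_rect2 <= cfg$rectum_air_radius^2] <- tissue_labels[["air"]]

    # prostate ellipsoid, then coaxial urethra restricted to the prostate
    pr <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
    lab[pr] <- tissue_labels[["prostate"]]
    ur <- pr & (X^2 + Y^2 <= cfg$urethra_radius^2)
    lab[ur] <- tissue_labels[["urethra"]]

    apps <- place_applicators(cfg, semi, grid)
  })

  model <- structure(list(
    grid = grid_like(grid, lab),
    labels = tissue_labels,
    properties = tissue_table(),
    blood = blood_properties(),
    applicators = apps,
    frequency = cfg$frequency,
    semiaxes = semi,
    config = cfg,
    seed = seed
  ), class = "tbt_model")
  model$dwells <- candidate_dwells(model)
  model
}

# template-grid applicator placement with farthest-point selection and
# seeded jitter; transverse positions snapped to the voxel lattice so the
# catheter axis passes through voxel centres
place_applicators <- function(cfg, semi, grid) {
  a <- semi[1] - cfg$applicator_margin
  b <- semi[2] - cfg$applicator_margin
  ts <- cfg$template_spacing
  gx <- seq(-floor(a / ts), floor(a / ts)) * ts
  gy <- seq(-floor(b / ts), floor(b / ts)) * ts
  cand <- expand.grid(x = gx, y = gy)
  inside <- (cand$x / a)^2 + (cand$y / b)^2 <= 1
  clear <- sqrt(cand$x^2 + cand$y^2) >= cfg$urethra_margin
  cand <- cand[inside & clear, , drop = FALSE]
  n <- cfg$n_applicators
  if (nrow(cand) < n)
    stop("geometry error: template offers fewer positions than requested applicators")

  # farthest-point sampling, seeded start on the periphery
  r <- sqrt(cand$x^2 + cand$y^2)
  start <- which.max(r + stats::runif(nrow(cand), 0, 1e-3))
  sel <- start
  d2min <- (cand$x - cand$x[start])^2 + (cand$y - cand$y[start])^2
  while (length(sel) < n) {
    nxt <- which.max(d2min)
    sel <- c(sel, nxt)
    d2 <- (cand$x - cand$x[nxt])^2 + (cand$y - cand$y[nxt])^2
    d2min <- pmin(d2min, d2)
  }
  px <- cand$x[sel] + stats::rnorm(n, 0, cfg$jitter_sd)
  py <- cand$y[sel] + stats::rnorm(n, 0, cfg$jitter_sd)

  # snap to the voxel-centre lattice in the template plane
  ax <- grid_axes(grid)
  px <- ax$x[pmin(pmax(round(world_to_index(grid, cbind(px, 0, 0))[, 1]), 1),
                  grid$shape[1])]
  py <- ax$y[pmin(pmax(round(world_to_index(grid, cbind(0, py, 0))[, 2]), 1),
                  grid$shape[2])]

  zmin <- ax$z[1] + grid$spacing[3]
  zmax <- ax$z[length(ax$z)] - grid$spacing[3]
  # electrode pair centred on the prostate mid-plane: proximal then distal,
  # 20 mm segments separated by a 5 mm gap
  half <- cfg$electrode_length + cfg$electrode_gap / 2    # 22.5 mm
  lapply(seq_len(cfg$n_applicators), function(i) {
    p0 <- c(px[i], py[i], zmin)
    p1 <- c(px[i], py[i], zmax)
    if (abs(px[i]) > max(abs(ax$x)) || abs(py[i]) > max(abs(ax$y)))
      stop("geometry error: applicator track outside domain")
    s_of <- function(z) z - zmin
    el <- data.frame(
      s_start = c(s_of(-half), s_of(cfg$electrode_gap / 2)),
      s_end   = c(s_of(-cfg$electrode_gap / 2), s_of(half))
    )
    applicator(sprintf("A%02d", i), p0, p1, el, radius = cfg$catheter_radius,
               coating_thickness = cfg$coating_thickness)
  })
}

# candidate dwell positions: along each track inside the prostate with a
# surface margin, spaced by dwell_step
candidate_dwells <- function(model) {
  cfg <- model$config
  semi <- model$semiaxes
  rows <- lapply(model$applicators, function(app) {
    x <- app$p0[1]; y <- app$p0[2]
    q <- 1 - (x / semi[1])^2 - (y / semi[2])^2
    if (q <= 0) return(NULL)
    zext <- semi[3] * sqrt(q) - cfg$dwell_margin
    if (zext <= 0) return(NULL)
    z <- seq(-zext, zext, by = cfg$dwell_step)
    data.frame(applicator = app$id, x = x, y = y, z = z,
               s = z - app$p0[3], weight = 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Organ mask from the label grid
#' @param model a `tbt_model`.
#' @param tissue tissue name (see [tissue_labels]).
#' @return logical array over the grid.
#' @export
organ_mask <- function(model, tissue) {
  model$grid$values == model$labels[[tissue]]
}

#' Rasterize electrodes to voxel index sets
#'
#' Maps every electrode to the set of voxels whose centres lie within the
#' electrode cylinder (catheter radius around the track segment).
#'
#' @param model a `tbt_model`.
#' @return named list of integer vectors (1-based linear voxel indices), one
#'   per electrode, in the order of [electrode_table()].
#' @export
rasterize_electrodes <- function(model) {
  grid <- model$grid
  ax <- grid_axes(grid)
  et <- electrode_table(model)
  out <- vector("list", nrow(et))
  names(out) <- et$electrode
  for (r in seq_len(nrow(et))) {
    p0 <- c(et$x0[r], et$y0[r], et$z0[r])
    p1 <- c(et$x1[r], et$y1[r], et$z1[r])
    rad <- et$radius[r]
    lo <- pmin(p0, p1) - rad; hi <- pmax(p0, p1) + rad
    ii <- which(ax$x >= lo[1] - grid$spacing[1] & ax$x <= hi[1] + grid$spacing[1])
    jj <- which(ax$y >= lo[2] - grid$spacing[2] & ax$y <= hi[2] + grid$spacing[2])
    kk <- which(ax$z >= lo[3] - grid$spacing[3] & ax$z <= hi[3] + grid$spacing[3])
    if (!length(ii) || !length(jj) || !length(kk))
      stop(sprintf("resolution error: electrode %s has no voxels", et$electrode[r]))
    pts <- as.matrix(expand.grid(x = ax$x[ii], y = ax$y[jj], z = ax$z[kk]))
    d <- pt_segment_dist(pts, p0, p1)
    keep <- d <= rad
    if (!any(keep))
      stop(sprintf("resolution error: electrode %s has no voxels", et$electrode[r]))
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[keep, , drop = FALSE]
    out[[r]] <- sort(idx[, 1] + grid$shape[1] * (idx[, 2] - 1) +
                       grid$shape[1] * grid$shape[2] * (idx[, 3] - 1))
  }
  out
}

# distance from points (n x 3) to segment p0-p1
pt_segment_dist <- function(pts, p0, p1) {
  u <- p1 - p0
  len2 <- sum(u^2)
  w <- sweep(pts, 2, p0, "-")
  t <- pmin(pmax((w %*% u) / len2, 0), 1)
  proj <- outer(as.numeric(t), u)
  sqrt(rowSums((w - proj)^2))
}

#' Per-voxel property grids
#'
#' Expands the tissue property table over the label grid.  Perfusion is
#' returned in SI volumetric units (m^3 blood / kg tissue / s).
#'
#' @param model a `tbt_model`.
#' @return list of arrays: `sigma` (S/m), `eps_r`, `rho` (kg/m^3),
#'   `c` (J/kg/K), `k` (W/m/K), `omega_si` (m^3/kg/s).
#' @export
property_grids <- function(model) {
  tab <- model$properties
  lab <- model$grid$values
  codes <- sort(unique(as.vector(lab)))
  name_of <- names(model$labels)[match(codes, model$labels)]
  if (anyNA(name_of)) stop("lookup error: label grid contains unknown codes")
  missing <- setdiff(name_of, tab$tissue)
  if (length(missing))
    stop("lookup error: no properties for tissue(s): ",
         paste(missing, collapse = ", "))
  # map label code -> table row via a dense lookup vector
  lut_row <- rep(NA_integer_, max(codes))
  lut_row[codes] <- match(name_of, tab$tissue)
  rows <- lut_row[lab]
  shape <- dim(lab)
  list(sigma = array(tab$sigma[rows], shape),
       eps_r = array(tab$eps_r[rows], shape),
       rho = array(tab$rho[rows], shape),
       c = array(tab$c[rows], shape),
       k = array(tab$k[rows], shape),
       omega_si = array(perfusion_si(tab$omega[rows]), shape))
}

#' @export
print.tbt_model <- function(x, ...) {
  cat(sprintf("<tbt_model> %d x %d x %d grid @ %.2g mm, %d applicators (%d electrodes)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              max(x$grid$spacing), length(x$applicators),
              sum(vapply(x$applicators, function(a) nrow(a$electrodes), 1L))))
  invisible(x)
}
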