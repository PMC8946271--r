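#' Volume fraction at or above a threshold
#'
#' `V_x`-style metric: the percentage of an organ's voxels with value at or
#' above the threshold (ties count as covered).
#'
#' @param values scalar array (dose Gy or temperature C).
#' @param mask logical array selecting the organ.
#' @param threshold scalar threshold.
#' @return percent of organ volume (0-100).
#' @export
volume_fraction_at <- function(values, mask, threshold) {
  n <- sum(mask)
  if (n == 0) stop("metric error: empty mask")
  100 * sum(values[mask] >= threshold) / n
}

#' Dose to the hottest x cubic centimetres
#'
#' `D_xcc`: the maximum dose d such that at least `x_cc` of the organ
#' receives >= d.  Computed by sorting voxel values in descending order and
#' interpolating linearly on cumulative volume.
#'
#' @param values scalar array.
#' @param mask logical array selecting the organ.
#' @param x_cc volume of interest (cc), `0 < x_cc <=` organ volume.
#' @param voxel_cc volume per voxel (cc).
#' @return the D_xcc value (same units as `values`).
#' @export
dose_at_volume_cc <- function(values, mask, x_cc, voxel_cc) {
  n <- sum(mask)
  if (n == 0) stop("metric error: empty mask")
  if (x_cc <= 0) stop("metric error: x_cc must be > 0")
  if (x_cc > n * voxel_cc + 1e-9)
    stop("metric error: x_cc exceeds organ volume")
  d <- sort(values[mask], decreasing = TRUE)
  m <- x_cc / voxel_cc          # voxels of interest, possibly fractional
  if (m <= 1) return(d[1])
  lo <- floor(m); hi <- ceiling(m)
  if (lo == hi || hi > n) return(d[min(lo, n)])
  d[lo] + (m - lo) * (d[hi] - d[lo])
}

#' Temperature percentiles T10/T50/T90
#'
#' `T_p`: the maximum temperature reached by at least p percent of the organ
#' volume, with the same descending-sort interpolation rule as
#' [dose_at_volume_cc()].
#'
#' @param values temperature array (degrees C).
#' @param mask logical array selecting the organ.
#' @param p percentages (default 10, 50, 90).
#' @return named numeric vector (e.g. `T10`, `T50`, `T90`).
#' @export
temperature_percentiles <- function(values, mask, p = c(10, 50, 90)) {
  n <- sum(mask)
  if (n == 0) stop("metric error: empty mask")
  d <- sort(values[mask], decreasing = TRUE)
  out <- vapply(p, function(pp) {
    m <- pp / 100 * n
    if (m <= 1) return(d[1])
    lo <- floor(m); hi <- ceiling(m)
    if (lo == hi || hi > n) return(d[min(lo, n)])
    d[lo] + (m - lo) * (d[hi] - d[lo])
  }, numeric(1))
  names(out) <- paste0("T", p)
  out
}

#' Cumulative dose- or temperature-volume histogram
#'
#' @param values scalar array.
#' @param mask logical array selecting the organ.
#' @param thresholds increasing vector of thresholds; defaults to an even
#'   grid from 0 to the organ maximum.
#' @param voxel_cc volume per voxel (cc), for the absolute-volume column.
#' @return data.frame with `threshold`, `fraction` (of organ volume at or
#'   above), and `cc`.
#' @export
dvh_curve <- function(values, mask, thresholds = NULL, voxel_cc = NA_real_) {
  n <- sum(mask)
  if (n == 0) stop("metric error: empty mask")
  v <- values[mask]
  if (is.null(thresholds))
    thresholds <- seq(0, max(v), length.out = 201)
  frac <- vapply(thresholds, function(t) sum(v >= t) / n, numeric(1))
  data.frame(threshold = thresholds, fraction = frac, cc = frac * n * voxel_cc)
}

#' 3D gamma-index comparison of two scalar fields
#'
#' For every evaluated voxel in the analysis region, the gamma index is the
#' minimum over reference positions within the search radius of
#' `sqrt((value difference / crit)^2 + (distance / dta_mm)^2)`, where `crit`
#' is `dd_percent` % of the global normalization value (by default the
#' maximum of the reference field).  The reference field is sampled on a
#' sub-voxel lattice by trilinear interpolation so that distance-to-agreement
#' criteria finer than the grid spacing remain meaningful.
#'
#' @param reference reference `voxel_grid` (or array on `grid`).
#' @param evaluated evaluated `voxel_grid` (same raster).
#' @param dd_percent dose-difference criterion (% of normalization).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param normalization value whose `dd_percent` defines the difference
#'   criterion; default `max(reference)`.
#' @param low_cutoff analysis region: evaluate only voxels with reference
#'   value above `low_cutoff * normalization` (set 0 to evaluate all).
#' @param subsample sub-voxel sampling factor: when the grid spacing is
#'   coarser than `dta_mm`, the reference is sampled on a lattice of step
#'   `min(spacing)/subsample`; otherwise the voxel spacing itself is used.
#' @param search_radius_factor search radius as a multiple of `dta_mm`.
#' @return list with `gamma` (`voxel_grid`, NA outside the analysis region),
#'   `pass_rate` (% of analysed voxels with gamma <= 1), `n_analysed`, and
#'   the criteria used.
#' @export
gamma_index_3d <- function(reference, evaluated, dd_percent = 5,
                           dta_mm = 0.5, normalization = NULL,
                           low_cutoff = 0.1, subsample = 3,
                           search_radius_factor = 3) {
  if (!inherits(reference, "voxel_grid") || !inherits(evaluated, "voxel_grid"))
    stop("reference and evaluated must be voxel_grid objects")
  stopifnot_same_raster(reference, evaluated)
  if (dd_percent <= 0 || dta_mm <= 0) stop("criteria must be positive")
  if (is.null(normalization)) normalization <- max(reference$values)
  if (normalization <= 0) stop("normalization must be positive")
  crit <- dd_percent / 100 * normalization
  analyse <- reference$values > low_cutoff * normalization
  if (!any(analyse)) stop("analysis region is empty")
  step <- if (min(reference$spacing) > dta_mm && subsample > 1)
    min(reference$spacing) / subsample else min(reference$spacing)
  radius <- search_radius_factor * dta_mm
  if (min(reference$spacing) > dta_mm && subsample <= 1)
    warning("grid spacing coarser than dta without subsampling; gamma may be overestimated")
  g <- .gamma_index_cpp(as.numeric(reference$values),
                        as.numeric(evaluated$values),
                        reference$shape, reference$spacing,
                        crit, dta_mm, radius, step,
                        as.integer(analyse))
  g <- array(g, dim = reference$shape)
  # the 1e-9 guard admits points sitting exactly on the gamma = 1 surface
  pass <- 100 * sum(g[analyse] <= 1 + 1e-9, na.rm = TRUE) / sum(analyse)
  list(gamma = grid_like(reference, g), pass_rate = pass,
       n_analysed = sum(analyse),
       criteria = list(dd_percent = dd_percent, dta_mm = dta_mm,
                       normalization = normalization,
                       low_cutoff = low_cutoff, step_mm = step,
                       search_radius_mm = radius))
}
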