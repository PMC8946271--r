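#' Regular voxel grid
#'
#' A minimal raster container for all scalar, label and vector fields used by
#' the planning pipeline.  World coordinates are in millimetres; `origin` is
#' the world position of the centre of the first voxel (R index `[1,1,1]`),
#' and the world-to-index mapping is the invertible affine
#' `world = origin + (index - 1) * spacing`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric length 3, voxel size in mm (all > 0).
#' @param origin numeric length 3, world position (mm) of the first voxel
#'   centre.  Defaults to centring the grid on the world origin.
#' @param values array of dim `shape`, or a single value to fill with.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = NULL, values = 0) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape <= 0L))
    stop("shape must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  if (length(values) == 1L) values <- array(values, dim = shape)
  if (!identical(as.integer(dim(values)), shape))
    stop("values array does not match shape")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 values = values),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s mm, %s values\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              typeof(x$values)))
  invisible(x)
}

#' Voxel-centre coordinates along each axis
#' @param grid a `voxel_grid`.
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

#' Convert world coordinates (mm) to fractional 1-based voxel indices
#' @param grid a `voxel_grid`.
#' @param xyz numeric matrix (n x 3) or vector of length 3.
#' @return matrix (n x 3) of fractional indices.
#' @export
world_to_index <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

#' Convert 1-based voxel indices to world coordinates (mm)
#' @param grid a `voxel_grid`.
#' @param ijk numeric matrix (n x 3) or vector of length 3.
#' @return matrix (n x 3) of world coordinates (mm).
#' @export
index_to_world <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Voxel volume in cubic centimetres
#' @param grid a `voxel_grid`.
#' @return scalar, cc per voxel.
#' @export
voxel_cc <- function(grid) prod(grid$spacing) / 1000

#' Replace the value array of a grid, keeping the raster
#' @param grid a `voxel_grid`.
#' @param values array of matching dim, or single fill value.
#' @return a `voxel_grid` on the same raster.
#' @export
grid_like <- function(grid, values) {
  voxel_grid(grid$shape, grid$spacing, grid$origin, values)
}

#' Logical mask of the outer boundary voxels of a grid
#' @param shape integer length 3.
#' @return logical array, TRUE on the six outer faces.
#' @export
boundary_mask <- function(shape) {
  m <- array(FALSE, dim = shape)
  m[c(1, shape[1]), , ] <- TRUE
  m[, c(1, shape[2]), ] <- TRUE
  m[, , c(1, shape[3])] <- TRUE
  m
}

same_raster <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_raster <- function(a, b) {
  if (!same_raster(a, b))
    stop("grids are not on the same raster (shape/spacing/origin mismatch)")
  invisible(TRUE)
}

# run expr with a private RNG stream derived from seed, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}
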