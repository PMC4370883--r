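#' Construct a density grid
#'
#' A `density_grid` is a 3-D scalar field on a regular orthogonal lattice.
#' `values` is an (nx, ny, nz) array; `origin` is the world coordinate (in
#' Angstrom) of the CENTER of voxel (1,1,1) (index (0,0,0) in file terms);
#' voxel (i,j,k) (1-based) sits at `origin + (i-1, j-1, k-1) * voxel_size`.
#' This center-of-voxel origin convention is used consistently by every
#' function in the package.
#'
#' @param values numeric 3-D array of density values.
#' @param voxel_size numeric length-1 or length-3, voxel edge lengths in
#'   Angstrom (all > 0).
#' @param origin numeric length-3, world coordinate of the first voxel
#'   center, Angstrom.
#' @param axis_order integer length-3, the file-axis to crystal-axis mapping
#'   (MAPC, MAPR, MAPS) the grid was read with; informational.
#'
#' @return object of class `density_grid`.
#' @export
density_grid <- function(values, voxel_size, origin = c(0, 0, 0),
                         axis_order = c(1L, 2L, 3L)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size components must be positive")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite 3-vector")
  if (any(!is.finite(values))) stop("grid values must be finite")
  g <- list(values = values, voxel_size = voxel_size, origin = origin,
            axis_order = as.integer(axis_order))
  class(g) <- "density_grid"
  g
}

#' Grid dimensions
#' @param grid a `density_grid`.
#' @return integer length-3 (nx, ny, nz).
#' @export
grid_dims <- function(grid) dim(grid$values)

# population (1/N) standard deviation over all voxels
grid_sigma <- function(grid) {
  v <- as.numeric(grid$values)
  sqrt(mean((v - mean(v))^2))
}

# world coordinates of voxel centers along each axis
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$voxel_size[axis]
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d voxels, voxel %.3g x %.3g x %.3g A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  origin (first voxel center): [%.2f, %.2f, %.2f] A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g, sd %.4g\n",
              min(x$values), mean(x$values), max(x$values), grid_sigma(x)))
  invisible(x)
}
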