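# Gaussian-kernel map simulation: each selected atom deposits an isotropic
# 3-D Gaussian evaluated at voxel centers, truncated beyond a stated number
# of standard deviations. "Resolution" is interpreted as the kernel FWHM by
# default, so kernel_sigma = resolution / (2*sqrt(2*log(2))).

#' Parameters for Gaussian-kernel map simulation
#'
#' @param resolution nominal map resolution in Angstrom (> 0), realized as
#'   the full width at half maximum of the blurring Gaussian by default.
#' @param voxel_size voxel edge in Angstrom (default 2).
#' @param padding margin added around the model bounding box, Angstrom;
#'   default `2 * resolution` (always at least `3 * kernel_sigma` plus one
#'   voxel, so truncated kernels fit).
#' @param kernel_sigma_factor ratio kernel_sigma / resolution; default
#'   `1 / (2 sqrt(2 ln 2))` (FWHM convention).
#' @param weight_mode `"atomic_number"` (kernel mass proportional to Z,
#'   default — heavy atoms dominate electron scattering) or `"uniform"`.
#' @param cutoff_sigma truncation radius in kernel standard deviations
#'   (default 4; mass error < 1e-4).
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(resolution, voxel_size = 2,
                              padding = 2 * resolution,
                              kernel_sigma_factor = 1 / (2 * sqrt(2 * log(2))),
                              weight_mode = c("atomic_number", "uniform"),
                              cutoff_sigma = 4) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be positive (Angstrom)")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  weight_mode <- match.arg(weight_mode)
  sigma <- kernel_sigma_factor * resolution
  if (sigma <= 0) stop("kernel sigma must be positive")
  padding <- max(padding, 3 * sigma + voxel_size)
  p <- list(resolution = resolution, voxel_size = voxel_size,
            padding = padding, kernel_sigma_factor = kernel_sigma_factor,
            kernel_sigma = sigma, weight_mode = weight_mode,
            cutoff_sigma = cutoff_sigma)
  class(p) <- "simulation_params"
  p
}

# approximate atomic numbers for kernel weights
.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

atom_weights <- function(model, params) {
  if (params$weight_mode == "uniform") return(rep(1, nrow(model)))
  z <- .atomic_numbers[toupper(model$element)]
  z[is.na(z)] <- 6  # unknown elements counted as carbon
  as.numeric(z)
}

resolve_selection <- function(model, selection) {
  if (is.null(selection)) sel <- rep(TRUE, nrow(model))
  else if (is.function(selection)) sel <- selection(model)
  else sel <- selection
  sel <- as.logical(sel)
  if (length(sel) != nrow(model)) stop("selection length must match atom count")
  sel
}

#' Simulate a density map from an atomic model
#'
#' Deposits one isotropic Gaussian per selected atom (standard deviation
#' `kernel_sigma`, integrated weight 1 or Z depending on `weight_mode`) on a
#' grid spanning the selection's bounding box plus padding. Voxel centers are
#' snapped onto a lattice aligned with the world coordinate origin, so maps
#' of translated copies of a model live on the same lattice.
#'
#' @param model an [atomic_model()].
#' @param params a [simulation_params()].
#' @param selection `NULL` (all atoms), a logical vector, or a predicate
#'   function taking the model and returning a logical vector.
#' @return a [density_grid()].
#' @export
simulate_map <- function(model, params, selection = NULL) {
  sel <- resolve_selection(model, selection)
  if (!any(sel)) stop("no atoms selected for map simulation")
  xyz <- coords(model)[sel, , drop = FALSE]
  v <- params$voxel_size
  lo <- apply(xyz, 2, min) - params$padding
  hi <- apply(xyz, 2, max) + params$padding
  origin <- v * floor(lo / v)
  dims <- pmax(2L, as.integer(ceiling((hi - origin) / v)) + 1L)
  template <- density_grid(array(0, dims), voxel_size = v, origin = origin)
  simulate_map_on_grid(model, template, params, selection)
}

#' Simulate a density map on an existing grid
#'
#' Same kernel arithmetic as [simulate_map()] but the lattice (dims, origin,
#' voxel size) is copied from `template`; used to back-calculate the model
#' map on an observed map's grid so the correlation sum is voxel-aligned.
#' Atoms whose truncated kernel lies entirely outside the grid contribute
#' nothing.
#'
#' @inheritParams simulate_map
#' @param template a [density_grid()] supplying the lattice.
#' @return a [density_grid()] on `template`'s lattice.
#' @export
simulate_map_on_grid <- function(model, template, params, selection = NULL) {
  stopifnot(inherits(template, "density_grid"))
  sel <- resolve_selection(model, selection)
  if (!any(sel)) stop("no atoms selected for map simulation")
  xyz <- coords(model)[sel, , drop = FALSE]
  w <- atom_weights(model, params)[sel]
  dims <- dim(template$values)
  vals <- cpp_deposit(xyz, w, template$origin, template$voxel_size,
                      dims, params$kernel_sigma, params$cutoff_sigma)
  density_grid(array(vals, dims), voxel_size = template$voxel_size,
               origin = template$origin)
}

#' Cube-shaped artificial density map (negative control)
#'
#' Builds, on `template`'s lattice, a map that is `level` inside an
#' axis-aligned cube and 0 outside. Used as a deliberately wrong map
#' restraint: a shape uncorrelated with the molecule should degrade, not
#' improve, a refinement.
#'
#' @param template a [density_grid()] supplying the lattice.
#' @param edge cube edge length, Angstrom (> 0).
#' @param center cube center, length-3 world coordinates (Angstrom).
#' @param level density value inside the cube (default 1).
#' @return a [density_grid()].
#' @export
make_cube_map <- function(template, edge, center, level = 1) {
  stopifnot(inherits(template, "density_grid"), edge > 0)
  center <- as.numeric(center)
  half <- edge / 2
  cx <- abs(grid_axis_coords(template, 1) - center[1]) <= half
  cy <- abs(grid_axis_coords(template, 2) - center[2]) <= half
  cz <- abs(grid_axis_coords(template, 3) - center[3]) <= half
  if (!any(cx) || !any(cy) || !any(cz))
    stop("cube lies entirely outside the template grid")
  vals <- level * (outer(outer(as.numeric(cx), as.numeric(cy)),
                         as.numeric(cz)))
  density_grid(array(vals, dim(template$values)),
               voxel_size = template$voxel_size, origin = template$origin)
}
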