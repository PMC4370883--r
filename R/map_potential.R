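# The map restraint: cross-correlation C between observed and calculated
# maps, energy k_c * (1 - C), and the exact analytic gradient with respect
# to atomic coordinates (including the dependence of the calculated map's
# mean and standard deviation on the coordinates).

#' Default atom selection for the map potential
#'
#' Selects every atom that is not a pseudo atom and whose name does not
#' begin with `H` — i.e. the heavy atoms that dominate electron scattering.
#'
#' @param model an [atomic_model()].
#' @return logical vector, `TRUE` for selected atoms.
#' @export
default_selection <- function(model) {
  !model$is_pseudo & !startsWith(model$name, "H")
}

#' Parameters of the cross-correlation map potential
#'
#' @param k_c force-constant scale of the energy `k_c * (1 - C)` (energy
#'   units, >= 0; default 10).
#' @param sim a [simulation_params()] giving the kernel used to back-calculate
#'   the model map (shared with the map-simulation step so observed and
#'   calculated maps are commensurate).
#' @param selection atom predicate; default [default_selection()] (excludes
#'   hydrogens and pseudo atoms).
#' @return object of class `map_potential_params`.
#' @export
map_potential_params <- function(sim, k_c = 10, selection = default_selection) {
  stopifnot(inherits(sim, "simulation_params"))
  if (!is.numeric(k_c) || k_c < 0) stop("k_c must be >= 0")
  p <- list(k_c = k_c, sim = sim, selection = selection)
  class(p) <- "map_potential_params"
  p
}

#' Cross-correlation between two density grids
#'
#' Pearson correlation over all N voxels,
#' `C = (1/N) sum_i (m_i^obs - mean^obs)(m_i^calc - mean^calc) /
#' (sigma^obs sigma^calc)`, with population (1/N) means and standard
#' deviations taken over the full grid, no masking.
#'
#' @param obs,calc two [density_grid()]s with identical dimensions.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
cross_correlation <- function(obs, calc) {
  stopifnot(inherits(obs, "density_grid"), inherits(calc, "density_grid"))
  if (!identical(dim(obs$values), dim(calc$values)))
    stop("observed and calculated grids have different dimensions")
  a <- as.numeric(obs$values)
  b <- as.numeric(calc$values)
  a <- a - mean(a); b <- b - mean(b)
  so <- sqrt(mean(a^2)); sc <- sqrt(mean(b^2))
  if (so <= 0) stop("observed grid is flat (zero standard deviation)")
  if (sc <= 0) stop("calculated grid is flat (zero standard deviation)")
  mean(a * b) / (so * sc)
}

#' Map-potential energy and analytic gradient
#'
#' Back-calculates the model map on the observed grid, computes
#' `C = cross_correlation(obs, calc)`, the energy `k_c * (1 - C)` and the
#' exact gradient of that energy with respect to every atom's coordinates.
#' The chain rule runs through the kernel deposition:
#' `dC/dm_j^calc = (1/(N sigma^obs sigma^calc)) * [(m_j^obs - mean^obs) -
#' C (sigma^obs / sigma^calc)(m_j^calc - mean^calc)]`
#' — the second term carries the coordinate dependence of the calculated
#' map's mean and standard deviation (the dependence through the mean alone
#' cancels because the centered observed values sum to zero).
#'
#' @param model an [atomic_model()].
#' @param obs observed [density_grid()].
#' @param params a [map_potential_params()].
#' @param keep_calc also return the back-calculated grid as `calc`
#'   (default TRUE; the refinement loop disables it).
#' @return list with class `map_potential_result`: `C`, `energy`,
#'   `gradient` (n x 3 matrix, zero rows for unselected atoms), and, with
#'   `keep_calc`, the calculated grid `calc`.
#' @export
map_energy <- function(model, obs, params, keep_calc = TRUE) {
  stopifnot(inherits(params, "map_potential_params"))
  cache <- obs_cache(obs)
  res <- map_energy_core(model, cache, params)
  if (keep_calc)
    res$calc <- density_grid(array(res$mc, cache$dims),
                             voxel_size = obs$voxel_size, origin = obs$origin)
  res$mc <- NULL
  class(res) <- "map_potential_result"
  res
}

# precomputed observed-map statistics, shared across many evaluations
obs_cache <- function(obs) {
  stopifnot(inherits(obs, "density_grid"))
  mo <- as.numeric(obs$values)
  a <- mo - mean(mo)
  so <- sqrt(mean(a^2))
  if (so <= 0) stop("observed grid is flat (zero standard deviation)")
  list(a = a, so = so, origin = obs$origin, voxel = obs$voxel_size,
       dims = dim(obs$values))
}

map_energy_core <- function(model, cache, params) {
  sel <- resolve_selection(model, params$selection)
  if (!any(sel)) stop("no atoms selected for the map potential")
  xyz <- coords(model)[sel, , drop = FALSE]
  w <- atom_weights(model, params$sim)[sel]
  mc <- cpp_deposit(xyz, w, cache$origin, cache$voxel, cache$dims,
                    params$sim$kernel_sigma, params$sim$cutoff_sigma)
  cc <- cpp_cc_coef(cache$a, cache$so, mc, params$k_c)
  if (!(cc$sc > 0))
    stop("calculated map is flat: all selected atoms fall outside the ",
         "observed grid; recenter the model on the map")
  gsel <- cpp_deposit_grad(xyz, w, cache$origin, cache$voxel, cache$dims,
                           params$sim$kernel_sigma, params$sim$cutoff_sigma,
                           cc$gcoef)
  gradient <- matrix(0, nrow(model), 3)
  gradient[sel, ] <- gsel
  list(C = cc$C, energy = params$k_c * (1 - cc$C), gradient = gradient,
       mc = mc)
}
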