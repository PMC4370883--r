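# The packaged refinement study: refine a perturbed toy helix against its
# restraints, with and without simulated maps across a resolution ladder and
# against a cube-shaped control map, and report bundle precision/accuracy.
# This is the package's scaled-down analog of the classic resolution-vs-
# precision experiment for map-restrained refinement.

#' Default annealing schedule for the refinement studies
#'
#' A shortened schedule calibrated on the toy-helix fixtures: a hot
#' equilibration long enough that independent repeats decorrelate, a
#' 25-stage geometric ladder, and a deep quasi-Newton polish.
#'
#' @param seed base RNG seed.
#' @param polish_maxit polish iteration cap (default 1500).
#' @param ... further arguments passed to [annealing_schedule()].
#' @return an [annealing_schedule()].
#' @export
study_schedule <- function(seed = 1, polish_maxit = 1500, ...) {
  annealing_schedule(n_stages = 25, equil_time = 8, stage_time = 1,
                     dt = 0.02, seed = seed, polish_maxit = polish_maxit,
                     ...)
}

#' Resolution-ladder refinement study on the toy-helix fixture
#'
#' Builds the reference helix, perturbs it to `start_rmsd`, derives the
#' fixture restraints, then refines the same start under each condition:
#' restraints alone (`no_map`), restraints plus a simulated map at each
#' requested resolution (`res_<r>`), and optionally restraints plus the
#' cube-shaped control map (`cube`). Each condition runs the same
#' repeat-and-select protocol from the same base seed, so conditions differ
#' only in the map term.
#'
#' @param resolutions map resolutions in Angstrom (default 40, 25, 15, 10);
#'   may be empty.
#' @param seed base RNG seed for perturbation, restraint sampling and
#'   annealing.
#' @param n_repeats,n_select ensemble protocol (default 6 and 4).
#' @param schedule an [annealing_schedule()]; default [study_schedule()].
#' @param k_c map force constant for the study (default 20000; chosen so
#'   the map term is commensurate with the toy system's restraint and
#'   thermal energy scales — see the package vignette).
#' @param spec a [toy_spec()] (default: 40 residues, 4 atoms each).
#' @param start_rmsd starting perturbation, Angstrom RMSD (default 8).
#' @param include_cube add the cube-control condition (default TRUE).
#' @param cube_edge control cube edge, Angstrom (default 40).
#' @param noe_per_residue fixture NOE-like restraint density (default 2).
#' @return object of class `resolution_study`: a list with `conditions`
#'   (a data frame of per-condition precision/accuracy statistics),
#'   `ensembles` (named list of `refined_ensemble`s), `reference`, `start`,
#'   and the study parameters.
#' @export
resolution_study <- function(resolutions = c(40, 25, 15, 10), seed = 1,
                             n_repeats = 6, n_select = 4,
                             schedule = study_schedule(seed),
                             k_c = 20000, spec = toy_spec(),
                             start_rmsd = 8, include_cube = TRUE,
                             cube_edge = 40, noe_per_residue = 2) {
  ref <- build_toy_helix(spec)
  start <- perturb_model(ref, start_rmsd, seed = seed)
  rset <- toy_restraints(ref, noe_per_residue = noe_per_residue, seed = seed)
  protocol <- ensemble_protocol(n_repeats, n_select)
  # study grids use the tight 3-sigma kernel margin (the constructor's
  # floor) rather than the roomier 2 x resolution default: the truncated
  # kernels still fit, and coarse-resolution grids stay tractable
  study_sim <- function(res) simulation_params(res, padding = 0)
  # the map force varies on the kernel length scale, so coarse maps are
  # integrated with a proportionate multiple-time-stepping stride
  stride_for <- function(res) max(1L, as.integer(ceiling(res / 12)))
  conditions <- list(no_map = list(obs = NULL, sim = NULL, stride = 1L))
  for (res in resolutions) {
    sim <- study_sim(res)
    conditions[[sprintf("res_%g", res)]] <-
      list(obs = simulate_map(ref, sim, default_selection), sim = sim,
           stride = stride_for(res))
  }
  if (include_cube) {
    res0 <- if (length(resolutions)) min(resolutions) else 10
    sim <- study_sim(res0)
    tmpl <- simulate_map(ref, sim, default_selection)
    conditions$cube <- list(obs = make_cube_map(tmpl, edge = cube_edge,
                                                center = colMeans(coords(ref))),
                            sim = sim, stride = stride_for(res0))
  }
  ensembles <- list()
  rows <- list()
  for (name in names(conditions)) {
    cond <- conditions[[name]]
    mp <- if (!is.null(cond$obs)) map_potential_params(cond$sim, k_c = k_c)
    pot <- composite_potential(start, rset, cond$obs, mp,
                               map_stride = cond$stride)
    ens <- run_ensemble(start, pot, schedule, protocol)
    st <- ensemble_stats(ens$models, reference = ref)
    ensembles[[name]] <- ens
    rows[[name]] <- data.frame(
      condition = name,
      precision_mean = st$pairwise_rmsd_mean,
      precision_sd = st$pairwise_rmsd_sd,
      accuracy_mean = st$reference_rmsd_mean,
      accuracy_sd = st$reference_rmsd_sd,
      mean_C = mean(ens$C),
      min_energy = min(ens$energies),
      stringsAsFactors = FALSE)
  }
  out <- list(conditions = do.call(rbind, c(rows, make.row.names = FALSE)),
              ensembles = ensembles, reference = ref, start = start,
              restraints = rset, seed = seed, k_c = k_c,
              protocol = protocol, schedule = schedule)
  class(out) <- "resolution_study"
  out
}

#' @export
print.resolution_study <- function(x, ...) {
  cat(sprintf("resolution_study (seed %d, %d repeats -> %d selected per condition)\n",
              x$seed, x$protocol$n_repeats, x$protocol$n_select))
  df <- x$conditions
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-8s precision %5.2f +/- %4.2f A   accuracy %5.2f +/- %4.2f A   C %.4f\n",
                df$condition[i], df$precision_mean[i], df$precision_sd[i],
                df$accuracy_mean[i], df$accuracy_sd[i], df$mean_C[i]))
  invisible(x)
}
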