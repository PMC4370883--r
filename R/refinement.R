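# Simulated-annealing refinement: Cartesian velocity-Verlet dynamics under a
# geometric cooling ladder, velocities resampled from the Maxwell
# distribution at each stage start, followed by a gradient-based polish.
# Repeat-and-select ensemble generation on top.
#
# Units are internal reduced units: length in Angstrom, mass in atomic mass
# units, energy on a kcal/mol-like scale with kB = 1.9872e-3 energy/K;
# times (equil_time, stage_time, dt) are in the matching internal time unit.

.kB <- 1.9872e-3

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06)

atom_masses <- function(model) {
  m <- .atomic_masses[toupper(model$element)]
  m[is.na(m)] <- 12.011
  as.numeric(m)
}

#' Annealing schedule
#'
#' Geometric temperature ladder from `T_high` to `T_low` inclusive over
#' `n_stages` stages; at each stage velocities are resampled from the
#' Maxwell distribution at the stage temperature and dynamics run for
#' `stage_time`. A heating/equilibration block of `equil_time` at `T_high`
#' precedes the ladder, and a quasi-Newton polish follows it.
#'
#' @param T_high,T_low temperatures in Kelvin (default 3000 and 25).
#' @param n_stages number of cooling stages (default 200).
#' @param equil_time equilibration time at `T_high`, internal time units
#'   (default 50).
#' @param stage_time dynamics time per stage (default 0.5).
#' @param dt integration time step (default 0.002).
#' @param seed RNG seed; every random draw of the anneal flows from it.
#' @param polish_maxit maximum quasi-Newton iterations in the final polish
#'   (default 300).
#' @param polish_tol projected-gradient tolerance for the polish
#'   (default 1e-5).
#' @return object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(T_high = 3000, T_low = 25, n_stages = 200,
                               equil_time = 50, stage_time = 0.5, dt = 0.002,
                               seed = 1, polish_maxit = 300,
                               polish_tol = 1e-5) {
  if (!(T_high > T_low && T_low > 0)) stop("need T_high > T_low > 0")
  if (n_stages < 2) stop("need n_stages >= 2")
  if (dt <= 0 || stage_time <= 0) stop("dt and stage_time must be positive")
  s <- list(T_high = T_high, T_low = T_low, n_stages = as.integer(n_stages),
            equil_time = equil_time, stage_time = stage_time, dt = dt,
            seed = as.integer(seed), polish_maxit = as.integer(polish_maxit),
            polish_tol = polish_tol)
  class(s) <- "annealing_schedule"
  s
}

#' Composite refinement potential
#'
#' Builds the total energy/gradient function used by [anneal()]: the sum of
#' the restraint terms and (when an observed map is given) the
#' cross-correlation map potential.
#'
#' @param model an [atomic_model()] fixing atom identities and selections.
#' @param rset optional [restraint_set()].
#' @param obs optional observed [density_grid()].
#' @param map_params a [map_potential_params()]; required with `obs`.
#' @param map_stride evaluate the map term only every `map_stride`-th
#'   dynamics step, holding its force in between (default 1 = every step).
#'   A multiple-time-stepping shortcut for coarse maps, whose force varies
#'   on the kernel length scale and is far smoother than the restraint
#'   forces; the final polish always uses the full potential.
#' @return with `map_stride = 1`, a function taking an n x 3 coordinate
#'   matrix and returning `list(energy, gradient, C)` (`C` is `NA` without
#'   a map); with `map_stride > 1`, a `split_potential` object that
#'   [anneal()] integrates with the stride and polishes in full.
#' @export
composite_potential <- function(model, rset = NULL, obs = NULL,
                                map_params = NULL, map_stride = 1L) {
  if (!is.null(obs) && is.null(map_params))
    stop("map_params required when an observed map is supplied")
  force(model); force(rset); force(map_params)
  cache <- if (!is.null(obs)) obs_cache(obs)
  fast <- function(X) {
    if (is.null(rset))
      return(list(energy = 0, gradient = matrix(0, nrow(model), 3)))
    restraint_energy(set_coords(model, X), rset)
  }
  slow <- if (!is.null(cache)) function(X)
    map_energy_core(set_coords(model, X), cache, map_params)
  full <- function(X) {
    fe <- fast(X)
    E <- fe$energy; G <- fe$gradient; C <- NA_real_
    if (!is.null(slow)) {
      me <- slow(X)
      E <- E + me$energy; G <- G + me$gradient; C <- me$C
    }
    list(energy = E, gradient = G, C = C)
  }
  if (map_stride <= 1L || is.null(slow)) return(full)
  structure(list(full = full, fast = fast, slow = slow,
                 stride = as.integer(map_stride)),
            class = "split_potential")
}

as_full_potential <- function(potential) {
  if (inherits(potential, "split_potential")) potential$full else potential
}

maxwell_velocities <- function(n, masses, temperature) {
  matrix(rnorm(3 * n, sd = rep(sqrt(.kB * temperature / masses), 3)), n, 3)
}

run_dynamics <- function(X, V, potential, masses, n_steps, dt) {
  mm <- matrix(masses, nrow(X), 3)
  split <- inherits(potential, "split_potential")
  eval_force <- if (!split) {
    function(X, step) {
      ev <- potential(X)
      if (!is.finite(ev$energy) || any(!is.finite(ev$gradient))) return(NULL)
      -ev$gradient
    }
  } else {
    Fslow <- NULL
    function(X, step) {
      fe <- potential$fast(X)
      if (!is.finite(fe$energy) || any(!is.finite(fe$gradient))) return(NULL)
      if (is.null(Fslow) || step %% potential$stride == 0L) {
        se <- potential$slow(X)
        if (!is.finite(se$energy)) return(NULL)
        Fslow <<- -se$gradient
      }
      Fslow - fe$gradient
    }
  }
  F1 <- eval_force(X, 0L)
  if (is.null(F1)) return(NULL)
  for (s in seq_len(n_steps)) {
    V <- V + (0.5 * dt) * F1 / mm
    X <- X + dt * V
    F1 <- eval_force(X, s)
    if (is.null(F1)) return(NULL)
    V <- V + (0.5 * dt) * F1 / mm
  }
  list(X = X, V = V)
}

#' Simulated-annealing refinement of one model
#'
#' Heats the model to `T_high`, equilibrates, cools geometrically to `T_low`
#' over `n_stages` stages of Cartesian velocity-Verlet dynamics (velocities
#' resampled from the Maxwell distribution at every stage start), then
#' polishes with L-BFGS-B until the projected gradient falls below
#' `polish_tol`. Deterministic given `schedule$seed` (which is set via
#' `set.seed` at entry). If the dynamics produce a non-finite energy the
#' stage ladder is retried once from the start with half the time step.
#'
#' @param model0 starting [atomic_model()].
#' @param potential a function as built by [composite_potential()].
#' @param schedule an [annealing_schedule()].
#' @return list: `model` (refined [atomic_model()]), `energy` (polished
#'   energy), `C` (final map correlation, `NA` without a map),
#'   `seed` (the schedule seed).
#' @export
anneal <- function(model0, potential, schedule) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  X0 <- coords(model0)
  full <- as_full_potential(potential)
  ev0 <- full(X0)
  if (!is.finite(ev0$energy) || any(!is.finite(ev0$gradient)))
    stop("potential is not finite at the starting model")
  masses <- atom_masses(model0)
  n <- nrow(X0)
  temps <- schedule$T_high *
    (schedule$T_low / schedule$T_high)^((seq_len(schedule$n_stages) - 1) /
                                          (schedule$n_stages - 1))
  attempt <- function(dt) {
    set.seed(schedule$seed)
    X <- X0
    n_equil <- max(1L, round(schedule$equil_time / dt))
    V <- maxwell_velocities(n, masses, schedule$T_high)
    st <- run_dynamics(X, V, potential, masses, n_equil, dt)
    if (is.null(st)) return(NULL)
    X <- st$X
    n_stage <- max(1L, round(schedule$stage_time / dt))
    for (Tt in temps) {
      V <- maxwell_velocities(n, masses, Tt)
      st <- run_dynamics(X, V, potential, masses, n_stage, dt)
      if (is.null(st)) return(NULL)
      X <- st$X
    }
    X
  }
  X <- attempt(schedule$dt)
  if (is.null(X)) X <- attempt(schedule$dt / 2)
  if (is.null(X))
    stop("non-finite energy during annealing dynamics, even at half time step")
  # memoized fn/gr pair: L-BFGS-B asks for both at the same point
  last <- new.env(parent = emptyenv())
  evaluate <- function(p) {
    if (is.null(last$p) || !identical(p, last$p)) {
      last$ev <- full(matrix(p, n, 3))
      last$p <- p
    }
    last$ev
  }
  opt <- optim(as.numeric(X),
               fn = function(p) evaluate(p)$energy,
               gr = function(p) as.numeric(evaluate(p)$gradient),
               method = "L-BFGS-B",
               control = list(maxit = schedule$polish_maxit,
                              pgtol = schedule$polish_tol, factr = 10))
  Xf <- matrix(opt$par, n, 3)
  evf <- full(Xf)
  list(model = set_coords(model0, Xf), energy = evf$energy, C = evf$C,
       seed = schedule$seed)
}

#' Ensemble protocol: repeat count and selection size
#'
#' @param n_repeats independent annealing repeats (default 128).
#' @param n_select models kept (default 20); selection takes the
#'   lowest-energy `2 * n_select` candidates and greedily drops the model
#'   with the largest mean pairwise RMSD until `n_select` remain — the
#'   "lowest energy, smallest mutual RMS deviation" rule.
#' @return object of class `ensemble_protocol`.
#' @export
ensemble_protocol <- function(n_repeats = 128, n_select = 20) {
  if (!(n_select >= 1 && n_select <= n_repeats))
    stop("need 1 <= n_select <= n_repeats")
  p <- list(n_repeats = as.integer(n_repeats), n_select = as.integer(n_select))
  class(p) <- "ensemble_protocol"
  p
}

#' Repeat-and-select ensemble refinement
#'
#' Runs `n_repeats` independent anneals with seeds `schedule$seed + 0 ...
#' + n_repeats - 1` (results therefore independent of execution order),
#' then selects `n_select` models: rank by polished energy (ties broken by
#' lower seed), keep the lowest-energy `2 * n_select` candidates, and
#' greedily drop the candidate with the largest mean pairwise RMSD to the
#' rest until `n_select` remain. Repeats that fail are recorded and
#' skipped; an error is raised only if fewer than `n_select` succeed.
#'
#' @param model0 starting [atomic_model()].
#' @param potential as built by [composite_potential()].
#' @param schedule an [annealing_schedule()]; its seed is the base seed.
#' @param protocol an [ensemble_protocol()].
#' @param scope atom scope for the selection RMSDs (default [heavy_atoms()]).
#' @return object of class `refined_ensemble`: `models` (length
#'   `n_select`, energies non-decreasing), `energies`, `seeds`, `C`
#'   (map correlations), `n_failed`.
#' @export
run_ensemble <- function(model0, potential, schedule,
                         protocol = ensemble_protocol(), scope = heavy_atoms) {
  stopifnot(inherits(protocol, "ensemble_protocol"))
  results <- vector("list", protocol$n_repeats)
  for (r in seq_len(protocol$n_repeats)) {
    sch <- schedule
    sch$seed <- as.integer(schedule$seed + r - 1)
    results[[r]] <- tryCatch(anneal(model0, potential, sch),
                             error = function(e) e)
  }
  ok <- !vapply(results, inherits, logical(1), what = "error")
  n_failed <- sum(!ok)
  results <- results[ok]
  if (length(results) < protocol$n_select)
    stop("only ", length(results), " of ", protocol$n_repeats,
         " repeats succeeded; need at least ", protocol$n_select)
  energies <- vapply(results, `[[`, numeric(1), "energy")
  seeds <- vapply(results, function(r) as.integer(r$seed), integer(1))
  ord <- order(energies, seeds)
  cand <- head(ord, 2L * protocol$n_select)
  while (length(cand) > protocol$n_select) {
    mean_rmsd <- vapply(seq_along(cand), function(ci) {
      others <- cand[-ci]
      mean(vapply(others, function(oi)
        rmsd(results[[cand[ci]]]$model, results[[oi]]$model, scope),
        numeric(1)))
    }, numeric(1))
    drop_i <- which.max(mean_rmsd)
    cand <- cand[-drop_i]
  }
  cand <- cand[order(energies[cand], seeds[cand])]
  ens <- list(models = lapply(results[cand], `[[`, "model"),
              energies = energies[cand],
              seeds = seeds[cand],
              C = vapply(results[cand], `[[`, numeric(1), "C"),
              n_failed = n_failed)
  class(ens) <- "refined_ensemble"
  ens
}

#' @export
print.refined_ensemble <- function(x, ...) {
  cat(sprintf("refined_ensemble: %d models, energies %.3f .. %.3f\n",
              length(x$models), min(x$energies), max(x$energies)))
  invisible(x)
}

#' One-call refinement against restraints and an optional map
#'
#' Convenience wrapper: builds the composite potential and runs the
#' repeat-and-select protocol.
#'
#' @param model0 starting [atomic_model()].
#' @param rset a [restraint_set()].
#' @param obs optional observed [density_grid()].
#' @param map_params optional [map_potential_params()] (required with `obs`).
#' @param schedule an [annealing_schedule()].
#' @param protocol an [ensemble_protocol()].
#' @return a `refined_ensemble` (see [run_ensemble()]).
#' @export
refine_model <- function(model0, rset, obs = NULL, map_params = NULL,
                         schedule = annealing_schedule(),
                         protocol = ensemble_protocol()) {
  pot <- composite_potential(model0, rset, obs, map_params)
  run_ensemble(model0, pot, schedule, protocol)
}
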