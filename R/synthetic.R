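# Synthetic fixtures: parametric toy helices, controlled perturbations, and
# the standard fixture bundle (reference + perturbed starts + restraint
# table + simulated maps + cube control). The toy helix is a geometric
# stand-in for a nucleic-acid strand — helical regularity, a "P" backbone
# ring, a few atoms per residue — not a chemically meaningful RNA model.

#' Toy helix specification
#'
#' @param n_residues number of residues (default 40).
#' @param atoms_per_residue atoms per residue, >= 3; atom names are cycled
#'   from P, O5', C4', N1, C2, C3', O2', N3 (default 4).
#' @param rise helical rise per residue, Angstrom (default 2.8).
#' @param twist helical twist per residue, degrees (default 33).
#' @param radius backbone ("P") radius, Angstrom (default 9).
#' @return object of class `toy_spec`.
#' @export
toy_spec <- function(n_residues = 40, atoms_per_residue = 4, rise = 2.8,
                     twist = 33, radius = 9) {
  if (atoms_per_residue < 3) stop("need >= 3 atoms per residue")
  if (n_residues < 1) stop("need >= 1 residue")
  s <- list(n_residues = as.integer(n_residues),
            atoms_per_residue = as.integer(atoms_per_residue),
            rise = rise, twist = twist, radius = radius)
  class(s) <- "toy_spec"
  s
}

.toy_names <- c("P", "O5'", "C4'", "N1", "C2", "C3'", "O2'", "N3")

#' Build a deterministic toy helix
#'
#' Residue `m`, atom slot `t` (0-based) sits at cylindrical coordinates
#' radius `radius - 1.3 t`, angle `twist (m-1) + 12 t` degrees, height
#' `rise (m-1) + 0.45 t`: a regular single-stranded helix whose "P" atoms
#' form a ring of constant consecutive spacing. Atom slot 0 is always "P".
#'
#' @param spec a [toy_spec()].
#' @return an [atomic_model()].
#' @export
build_toy_helix <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  nm <- rep_len(.toy_names, spec$atoms_per_residue)
  t <- seq_len(spec$atoms_per_residue) - 1L
  rows <- expand.grid(t = t, m = seq_len(spec$n_residues))
  r <- spec$radius - 1.3 * rows$t
  ang <- (spec$twist * (rows$m - 1) + 12 * rows$t) * pi / 180
  z <- spec$rise * (rows$m - 1) + 0.45 * rows$t
  atomic_model(name = rep(nm, spec$n_residues),
               xyz = cbind(r * cos(ang), r * sin(ang), z),
               resname = "TOY", resno = rows$m, chain = "A")
}

#' Perturb a model to a target RMSD
#'
#' Adds a smooth displacement field — a few random low-frequency bending
#' modes along the chain plus small per-atom jitter — and rescales it so the
#' RMSD to the input after optimal superposition equals `target_rmsd`
#' within 2%. Different seeds give different deformations at the same RMSD.
#'
#' @param model an [atomic_model()].
#' @param target_rmsd target RMSD in Angstrom (>= 0).
#' @param seed RNG seed.
#' @return the perturbed [atomic_model()].
#' @export
perturb_model <- function(model, target_rmsd, seed = 1) {
  if (target_rmsd < 0) stop("target_rmsd must be >= 0")
  if (target_rmsd == 0) return(model)
  set.seed(seed)
  n <- nrow(model)
  s <- (seq_len(n) - 1) / max(1, n - 1)
  D <- matrix(0, n, 3)
  for (k in 1:3) {
    amp <- matrix(rnorm(3), 1)
    phase <- runif(3, 0, 2 * pi)
    for (d in 1:3) D[, d] <- D[, d] + amp[d] * sin(pi * k * s + phase[d]) / k
  }
  D <- D + matrix(rnorm(3 * n, sd = 0.05), n, 3)
  X0 <- coords(model)
  scale <- target_rmsd / sqrt(mean(rowSums(D^2)))
  for (it in 1:40) {
    pert <- set_coords(model, X0 + scale * D)
    cur <- rmsd(pert, model)
    if (abs(cur - target_rmsd) <= 0.01 * target_rmsd) break
    scale <- scale * target_rmsd / cur
  }
  pert
}

#' Restraints for a toy model derived from its reference geometry
#'
#' Builds the fixture restraint inventory: harmonic-equivalent bonds between
#' consecutive atoms (flat-bottom with `d_lo = d_hi` = reference distance),
#' backbone P-P distance restraints between consecutive residues, and a
#' seeded NOE-like sample of non-bonded atom pairs closer than `noe_range`
#' in the reference, all with +/- 10% bounds (bonds excepted) and
#' class-default force constants.
#'
#' @param reference the reference [atomic_model()].
#' @param noe_per_residue NOE-like restraints sampled per residue
#'   (default 2).
#' @param noe_range maximum reference distance for NOE-like pairs, Angstrom
#'   (default 6, the NOE observability range).
#' @param seed RNG seed for the NOE sample.
#' @return a [restraint_set()].
#' @export
toy_restraints <- function(reference, noe_per_residue = 2, noe_range = 6,
                           seed = 1) {
  X <- coords(reference)
  n <- nrow(reference)
  dmat <- as.matrix(dist(X))
  # consecutive-atom bonds at reference length
  bi <- seq_len(n - 1L)
  d0 <- dmat[cbind(bi, bi + 1L)]
  tab <- data.frame(res_i = reference$resno[bi], name_i = reference$name[bi],
                    res_j = reference$resno[bi + 1L],
                    name_j = reference$name[bi + 1L],
                    d_lo = d0, d_hi = d0, class = "bond")
  # consecutive P-P
  pidx <- which(reference$name == "P")
  if (length(pidx) > 1L) {
    pi1 <- pidx[-length(pidx)]; pi2 <- pidx[-1L]
    dp <- dmat[cbind(pi1, pi2)]
    tab <- rbind(tab, data.frame(
      res_i = reference$resno[pi1], name_i = "P",
      res_j = reference$resno[pi2], name_j = "P",
      d_lo = 0.9 * dp, d_hi = 1.1 * dp, class = "pp"))
  }
  # NOE-like sample: non-consecutive pairs within noe_range
  cand <- which(upper.tri(dmat) & dmat < noe_range & dmat > 0, arr.ind = TRUE)
  cand <- cand[abs(cand[, 1] - cand[, 2]) > 1L, , drop = FALSE]
  n_noe <- min(nrow(cand), noe_per_residue * max(reference$resno))
  if (n_noe > 0) {
    set.seed(seed)
    pick <- cand[sample.int(nrow(cand), n_noe), , drop = FALSE]
    dn <- dmat[pick]
    tab <- rbind(tab, data.frame(
      res_i = reference$resno[pick[, 1]], name_i = reference$name[pick[, 1]],
      res_j = reference$resno[pick[, 2]], name_j = reference$name[pick[, 2]],
      d_lo = 0.9 * dn, d_hi = 1.1 * dn, class = "noe"))
  }
  restraints_from_pairs(reference, tab)
}

#' Write the standard fixture bundle
#'
#' Builds everything the refinement studies need, with no external inputs:
#' a reference toy helix, perturbed starting models, a distance-restraint
#' table derived from the reference, simulated maps at each requested
#' resolution, a cube-shaped negative-control map on the finest map's
#' lattice, and a `manifest.txt` (plain `key = value` lines) listing every
#' file and generator parameter.
#'
#' @param out_dir output directory (created if missing).
#' @param resolutions map resolutions in Angstrom (default 40, 25, 15, 10).
#' @param seed base RNG seed.
#' @param spec a [toy_spec()].
#' @param n_starts number of perturbed starting models (default 2).
#' @param start_rmsd perturbation size in Angstrom RMSD (default 8).
#' @param noe_per_residue NOE-like restraints per residue (default 2).
#' @param cube_edge negative-control cube edge, Angstrom (default 40).
#' @return invisibly, a named list of the written paths plus the parsed
#'   manifest.
#' @export
make_standard_fixture <- function(out_dir, resolutions = c(40, 25, 15, 10),
                                  seed = 1, spec = toy_spec(), n_starts = 2,
                                  start_rmsd = 8, noe_per_residue = 2,
                                  cube_edge = 40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create fixture directory ", out_dir)
  ref <- build_toy_helix(spec)
  paths <- list(reference = file.path(out_dir, "reference.pdb"))
  write_pdb(ref, paths$reference)
  for (i in seq_len(n_starts)) {
    p <- file.path(out_dir, sprintf("start_%d.pdb", i))
    write_pdb(perturb_model(ref, start_rmsd, seed = seed + i), p)
    paths[[sprintf("start_%d", i)]] <- p
  }
  rset <- toy_restraints(ref, noe_per_residue = noe_per_residue, seed = seed)
  paths$restraints <- file.path(out_dir, "restraints.tbl")
  write_restraint_table(ref, rset, paths$restraints)
  finest <- NULL
  for (res in resolutions) {
    g <- simulate_map(ref, simulation_params(res), default_selection)
    p <- file.path(out_dir, sprintf("map_%g.ccp4", res))
    write_ccp4(g, p)
    paths[[sprintf("map_%g", res)]] <- p
    if (is.null(finest) || res == min(resolutions)) finest <- g
  }
  centroid <- colMeans(coords(ref))
  cube <- make_cube_map(finest, edge = cube_edge, center = centroid)
  paths$cube <- file.path(out_dir, "cube.ccp4")
  write_ccp4(cube, paths$cube)
  manifest <- c(
    sprintf("reference = %s", basename(paths$reference)),
    sprintf("restraints = %s", basename(paths$restraints)),
    vapply(seq_len(n_starts), function(i)
      sprintf("start_%d = start_%d.pdb", i, i), character(1)),
    vapply(resolutions, function(res)
      sprintf("map_%g = map_%g.ccp4", res, res), character(1)),
    sprintf("cube = %s", basename(paths$cube)),
    sprintf("seed = %d", seed),
    sprintf("n_residues = %d", spec$n_residues),
    sprintf("atoms_per_residue = %d", spec$atoms_per_residue),
    sprintf("rise = %g", spec$rise),
    sprintf("twist = %g", spec$twist),
    sprintf("radius = %g", spec$radius),
    sprintf("start_rmsd = %g", start_rmsd),
    sprintf("noe_per_residue = %g", noe_per_residue),
    sprintf("resolutions = %s", paste(resolutions, collapse = ",")),
    sprintf("cube_edge = %g", cube_edge))
  paths$manifest <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, paths$manifest)
  invisible(paths)
}
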