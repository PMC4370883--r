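# Superposition and RMSD machinery: least-squares (Kabsch) fitting and the
# bundle precision/accuracy statistics conventionally reported for NMR-style
# ensembles.

#' Heavy-atom scope
#'
#' Default atom scope for RMSD statistics: all non-hydrogen, non-pseudo
#' atoms ("all heavy atoms").
#'
#' @param model an [atomic_model()].
#' @return logical vector.
#' @export
heavy_atoms <- function(model) !model$is_hydrogen & !model$is_pseudo

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `target` over the scoped
#' atoms: the proper rotation (determinant +1; reflections excluded) and
#' translation minimizing the RMSD, found via singular value decomposition
#' of the covariance of the centered coordinate sets.
#'
#' @param mobile,target [atomic_model()]s with equal scoped atom counts
#'   (>= 3, non-collinear).
#' @param scope `NULL` (all atoms), logical vector, or predicate function;
#'   applied to both models.
#' @return list: `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom); the transform maps mobile coordinates as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, target, scope = NULL) {
  sm <- resolve_selection(mobile, scope)
  st <- resolve_selection(target, scope)
  P <- coords(mobile)[sm, , drop = FALSE]
  Q <- coords(target)[st, , drop = FALSE]
  if (nrow(P) != nrow(Q))
    stop("scoped atom counts differ (", nrow(P), " vs ", nrow(Q), ")")
  if (nrow(P) < 3L) stop("need at least 3 scoped atoms to superpose")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(P0, Q0)                    # sum_a p0 q0^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate geometry: superposition undefined")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # maps mobile frame -> target
  Pr <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Q0)^2)))
  list(rotation = R, translation = as.numeric(qc - R %*% pc), rmsd = rmsd)
}

#' RMSD between two models after optimal superposition
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, target, scope = NULL) {
  kabsch_superpose(mobile, target, scope)$rmsd
}

#' Apply a rigid transform to a model
#'
#' @param model an [atomic_model()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return the transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  set_coords(model, sweep(coords(model) %*% t(rotation), 2, -translation))
}

#' Ensemble precision and accuracy statistics
#'
#' Precision: mean and sample standard deviation of the pairwise RMSDs over
#' all unordered model pairs, each pair superposed independently (the NMR
#' bundle convention). Accuracy: per-model RMSD to `reference` when given.
#' With a single pair (or model) the standard deviation is reported as 0.
#'
#' @param models list of [atomic_model()]s (>= 2 for pairwise statistics).
#' @param reference optional [atomic_model()].
#' @param scope atom scope; default [heavy_atoms()].
#' @return object of class `ensemble_stats`: `pairwise_rmsd_mean`,
#'   `pairwise_rmsd_sd`, `pairwise_rmsds`, and (with a reference)
#'   `reference_rmsd_mean`, `reference_rmsd_sd`, `reference_rmsds`.
#' @export
ensemble_stats <- function(models, reference = NULL, scope = heavy_atoms) {
  if (length(models) < 2L) stop("need >= 2 models for pairwise statistics")
  n <- length(models)
  pr <- numeric(0)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      pr <- c(pr, rmsd(models[[i]], models[[j]], scope))
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  out <- list(pairwise_rmsd_mean = mean(pr), pairwise_rmsd_sd = sd0(pr),
              pairwise_rmsds = pr, n_models = n)
  if (!is.null(reference)) {
    rr <- vapply(models, rmsd, numeric(1), target = reference, scope = scope)
    out$reference_rmsd_mean <- mean(rr)
    out$reference_rmsd_sd <- sd0(rr)
    out$reference_rmsds <- rr
  }
  class(out) <- "ensemble_stats"
  out
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble of %d models: precision %.2f +/- %.2f A (pairwise RMSD)\n",
              x$n_models, x$pairwise_rmsd_mean, x$pairwise_rmsd_sd))
  if (!is.null(x$reference_rmsd_mean))
    cat(sprintf("  accuracy to reference: %.2f +/- %.2f A\n",
                x$reference_rmsd_mean, x$reference_rmsd_sd))
  invisible(x)
}
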