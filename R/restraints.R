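# Non-map energy terms: harmonic bonds and angles, flat-bottom distance
# restraints (NOE-like, hydrogen-bond, backbone P-P), and a soft excluded-
# volume repulsion between non-bonded pairs.

# package-convention force constants per restraint class (energy / A^2)
.class_k <- c(noe = 30, hbond = 50, pp = 5, bond = 500)

#' Construct a restraint set
#'
#' Holds every non-map energy term applied during refinement. Flat-bottom
#' distance restraints contribute 0 inside `[d_lo, d_hi]` and
#' `k (d - bound)^2` outside; bonds and angles are harmonic; atom pairs not
#' connected by a bond or angle that approach within `repulsion_radius`
#' feel a soft quadratic repulsion.
#'
#' @param distances data frame with columns `i, j` (1-based atom indices),
#'   `d_lo, d_hi` (Angstrom bounds), `k` (energy/A^2), `class` (one of
#'   `"noe"`, `"hbond"`, `"pp"`, `"bond"`); may be empty/NULL.
#' @param bonds data frame with columns `i, j, d0, k`; may be empty/NULL.
#' @param angles data frame with columns `i, j, k_atom` (j is the vertex),
#'   `theta0` (degrees), `k` (energy/rad^2); may be empty/NULL.
#' @param repulsion_radius Angstrom; pairs closer than this repel (default
#'   2.5; 0 disables).
#' @param repulsion_k energy/A^2 (default 10).
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(distances = NULL, bonds = NULL, angles = NULL,
                          repulsion_radius = 2.5, repulsion_k = 10) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (is.null(distances))
    distances <- cbind(empty(c("i", "j", "d_lo", "d_hi", "k")),
                       data.frame(class = character(0)))
  if (is.null(bonds)) bonds <- empty(c("i", "j", "d0", "k"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k_atom", "theta0", "k"))
  distances <- as.data.frame(distances)
  bonds <- as.data.frame(bonds)
  angles <- as.data.frame(angles)
  if (nrow(distances)) {
    if (any(distances$d_lo > distances$d_hi) || any(distances$d_lo < 0))
      stop("distance restraint bounds must satisfy 0 <= d_lo <= d_hi")
    if (any(distances$i == distances$j)) stop("restraint with i == j")
    if (any(distances$k < 0)) stop("negative force constant")
    key <- paste(pmin(distances$i, distances$j),
                 pmax(distances$i, distances$j), distances$class)
    if (anyDuplicated(key)) {
      warning("dropping duplicate distance restraints within a class")
      distances <- distances[!duplicated(key), , drop = FALSE]
    }
  }
  rs <- list(distances = distances, bonds = bonds, angles = angles,
             repulsion_radius = repulsion_radius, repulsion_k = repulsion_k)
  class(rs) <- "restraint_set"
  rs
}

check_indices <- function(rset, n) {
  idx <- c(rset$distances$i, rset$distances$j, rset$bonds$i, rset$bonds$j,
           rset$angles$i, rset$angles$j, rset$angles$k_atom)
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("restraint atom index out of range (model has ", n, " atoms)")
}

#' Restraint energy and analytic gradient
#'
#' @param model an [atomic_model()].
#' @param rset a [restraint_set()].
#' @return list: `energy` (scalar, >= 0), `gradient` (n x 3 matrix,
#'   energy/A), `terms` (named breakdown: bond, angle, distance, repulsion).
#' @export
restraint_energy <- function(model, rset) {
  stopifnot(inherits(rset, "restraint_set"))
  n <- nrow(model)
  check_indices(rset, n)
  im <- function(df, cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "integer"
    m - 1L  # to 0-based
  }
  res <- cpp_restraint_eg(
    coords(model),
    im(rset$bonds, c("i", "j")), as.numeric(rset$bonds$d0),
    as.numeric(rset$bonds$k),
    im(rset$angles, c("i", "j", "k_atom")),
    as.numeric(rset$angles$theta0) * pi / 180, as.numeric(rset$angles$k),
    im(rset$distances, c("i", "j")), as.numeric(rset$distances$d_lo),
    as.numeric(rset$distances$d_hi), as.numeric(rset$distances$k),
    rset$repulsion_radius, rset$repulsion_k)
  res
}

#' Build distance restraints from residue/atom-name pairs
#'
#' Resolves `(residue, atom name)` pairs to atom indices and appends
#' flat-bottom distance restraints with class-default force constants
#' (noe 30, hbond 50, pp 5, bond 500 energy/A^2).
#'
#' @param model an [atomic_model()].
#' @param pairs data frame with columns `res_i, name_i, res_j, name_j,
#'   d_lo, d_hi, class`.
#' @param rset optional existing [restraint_set()] to append to.
#' @return a [restraint_set()] with the new distance restraints appended.
#' @export
restraints_from_pairs <- function(model, pairs, rset = restraint_set()) {
  pairs <- as.data.frame(pairs)
  find_atom <- function(resno, name) {
    hit <- which(model$resno == resno & model$name == name)
    if (length(hit) == 0L)
      stop("no atom named '", name, "' in residue ", resno)
    hit[1]
  }
  if (nrow(pairs)) {
    i <- mapply(find_atom, pairs$res_i, pairs$name_i)
    j <- mapply(find_atom, pairs$res_j, pairs$name_j)
    k <- unname(.class_k[as.character(pairs$class)])
    if (any(is.na(k))) stop("unknown restraint class; use noe/hbond/pp/bond")
    new <- data.frame(i = i, j = j, d_lo = pairs$d_lo, d_hi = pairs$d_hi,
                      k = k, class = as.character(pairs$class))
    rset <- restraint_set(distances = rbind(rset$distances, new),
                          bonds = rset$bonds, angles = rset$angles,
                          repulsion_radius = rset$repulsion_radius,
                          repulsion_k = rset$repulsion_k)
  }
  rset
}

#' Read a distance-restraint table
#'
#' Whitespace-separated text, one restraint per line, with the one-line
#' header `res_i name_i res_j name_j d_lo d_hi class`.
#'
#' @param path path to the table.
#' @param model an [atomic_model()] used to resolve atom names.
#' @param rset optional [restraint_set()] to append to.
#' @return a [restraint_set()].
#' @export
read_restraint_table <- function(path, model, rset = restraint_set()) {
  if (!file.exists(path)) stop("restraint table not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("res_i", "name_i", "res_j", "name_j", "d_lo", "d_hi", "class")
  if (!all(need %in% names(tab)))
    stop("restraint table must have columns: ", paste(need, collapse = " "))
  restraints_from_pairs(model, tab, rset)
}

#' Write a distance-restraint table
#'
#' @param model the [atomic_model()] the indices refer to.
#' @param rset a [restraint_set()]; only its distance restraints are written.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_restraint_table <- function(model, rset, path) {
  d <- rset$distances
  tab <- data.frame(res_i = model$resno[d$i], name_i = model$name[d$i],
                    res_j = model$resno[d$j], name_j = model$name[d$j],
                    d_lo = round(d$d_lo, 6), d_hi = round(d$d_hi, 6),
                    class = d$class)
  write.table(tab, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
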