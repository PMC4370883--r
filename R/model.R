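#' Construct an atomic model
#'
#' An `atomic_model` is an ordered table of atom records: one row per atom
#' with name, element, residue name/number, chain, Cartesian coordinates in
#' Angstrom, and two flags used by atom selections: `is_hydrogen` and
#' `is_pseudo` (dummy atoms such as NMR pseudo-atoms). Atom order is
#' significant and preserved by all I/O.
#'
#' @param name character, atom names (e.g. `"P"`, `"C4'"`).
#' @param element character, element symbols; if `NA`, guessed from the first
#'   non-digit character of the atom name.
#' @param resname character, residue names.
#' @param resno integer, residue numbers.
#' @param chain character, chain identifiers.
#' @param xyz numeric matrix, n x 3 coordinates in Angstrom.
#' @param is_pseudo logical, marks pseudo/dummy atoms; default: atom name
#'   starts with `"Q"` or residue name is `"DUM"`.
#'
#' @return object of class `atomic_model` (a data frame).
#' @export
atomic_model <- function(name, xyz, element = NA_character_,
                         resname = "TOY", resno = 1L, chain = "A",
                         is_pseudo = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (n < 1L) stop("an atomic_model needs at least one atom")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  name <- rep_len(as.character(name), n)
  element <- rep_len(as.character(element), n)
  guess <- is.na(element) | !nzchar(trimws(element))
  element[guess] <- guess_element(name[guess])
  resname <- rep_len(as.character(resname), n)
  resno <- rep_len(as.integer(resno), n)
  chain <- rep_len(as.character(chain), n)
  if (is.null(is_pseudo)) {
    is_pseudo <- startsWith(name, "Q") | resname == "DUM"
  }
  is_pseudo <- rep_len(as.logical(is_pseudo), n)
  m <- data.frame(name = name, element = element, resname = resname,
                  resno = resno, chain = chain,
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  is_hydrogen = toupper(element) == "H",
                  is_pseudo = is_pseudo,
                  stringsAsFactors = FALSE)
  class(m) <- c("atomic_model", "data.frame")
  m
}

# first alphabetic character of the atom name; 'H' heuristic for blank
# element columns (adequate for the fixed-column PDB subset handled here)
guess_element <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(stripped, 1, 1))
  el[!nzchar(el)] <- "C"
  el
}

#' Coordinates of an atomic model as a matrix
#'
#' @param model an `atomic_model`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

#' Replace the coordinates of an atomic model
#'
#' @param model an `atomic_model`.
#' @param xyz n x 3 numeric matrix.
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == nrow(model), all(is.finite(xyz)))
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Number of atoms in a model
#' @param model an `atomic_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model)

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(unique(x$chain), collapse = ",")))
  cat(sprintf("  heavy: %d, hydrogens: %d, pseudo: %d\n",
              sum(!x$is_hydrogen & !x$is_pseudo),
              sum(x$is_hydrogen), sum(x$is_pseudo)))
  invisible(x)
}
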