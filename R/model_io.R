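#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB v3.3 subset) into an
#' [atomic_model()]. Only the first model of a multi-model file is used.
#' Hydrogen atoms are flagged from the element column when present, else from
#' a leading-H atom-name heuristic; pseudo atoms from Q-prefixed names or
#' residue name `DUM`.
#'
#' @param path path to a PDB file.
#' @return an `atomic_model`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot read PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no ATOM/HETATM records parsed from ", path)
  elem <- trimws(as.character(at$elesy))
  elem[is.na(elem)] <- ""
  atomic_model(name = trimws(at$elety),
               xyz = cbind(at$x, at$y, at$z),
               element = ifelse(nzchar(elem), elem, NA_character_),
               resname = trimws(at$resid),
               resno = as.integer(at$resno),
               chain = ifelse(is.na(at$chain), "A", as.character(at$chain)))
}

#' Write an atomic model to a PDB file
#'
#' Emits fixed-column ATOM records with coordinates to three decimals.
#'
#' @param model an `atomic_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  if (!inherits(model, "atomic_model") || nrow(model) < 1L)
    stop("model must be a non-empty atomic_model")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(model))),
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno,
                   resid = model$resname,
                   eleno = seq_len(nrow(model)),
                   elety = model$name,
                   chain = model$chain,
                   elesy = model$element)
  invisible(path)
}
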