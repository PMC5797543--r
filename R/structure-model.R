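# StructureModel: ordered chains -> residues -> atoms, stored as a flat atom
# table in file order. Residue numbering is taken verbatim from the source
# (no renumbering); insertion codes are preserved.

ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resseq",
               "icode", "x", "y", "z", "occupancy", "bfactor", "element")

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`,
#'   `element`. Row order is the iteration order and is preserved.
#' @param source identifier recorded on the object (file path or generator tag).
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, source = "in-memory") {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbol in atom table")
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicated atom (chain, resseq, icode, name, altloc): ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- model_chains(x)
  nres <- vapply(ch, function(c) nrow(model_residues(x, c)), integer(1))
  cat("StructureModel <", x$source, ">\n", sep = "")
  cat("  chains: ", paste(sprintf("%s (%d res)", ch, nres), collapse = ", "),
      "\n  atoms: ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

#' Chains of a StructureModel, in file order
#' @param model a `StructureModel`.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Residue table of one chain
#'
#' One row per residue in file order, with columns `resseq`, `icode`,
#' `resname` and the one-letter code `aa`.
#' @param model a `StructureModel`.
#' @param chain chain identifier.
#' @export
model_residues <- function(model, chain) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain not found: ", chain)
  keep <- !duplicated(paste(at$resseq, at$icode))
  data.frame(resseq = at$resseq[keep], icode = at$icode[keep],
             resname = at$resname[keep], aa = aa3to1(at$resname[keep]),
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain
#' @inheritParams model_residues
#' @export
model_sequence <- function(model, chain) {
  paste(model_residues(model, chain)$aa, collapse = "")
}

#' Select atoms from a StructureModel
#'
#' @param model a `StructureModel`.
#' @param chain optional chain id (vector allowed).
#' @param resseq optional residue numbers to keep.
#' @param atom_names optional atom names to keep; `backbone = TRUE` is a
#'   shortcut for N, CA, C, O.
#' @param backbone keep backbone atoms only.
#' @return atom data.frame (possibly empty), file order preserved.
#' @export
select_atoms <- function(model, chain = NULL, resseq = NULL,
                         atom_names = NULL, backbone = FALSE) {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resseq)) keep <- keep & at$resseq %in% resseq
  if (backbone) atom_names <- BACKBONE_ATOMS
  if (!is.null(atom_names)) keep <- keep & at$name %in% atom_names
  at[keep, , drop = FALSE]
}

#' @keywords internal
atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Replace a model's atom table, keeping class and source
#' @keywords internal
replace_atoms <- function(model, atoms) {
  structure_model(atoms, source = model$source)
}
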