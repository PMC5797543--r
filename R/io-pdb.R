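# PDB reading/writing. Parsing is delegated to bio3d; on top of it we apply
# the altloc policy (highest occupancy wins, ties resolved by file order),
# skip HETATM records and waters, and validate the fixed-width fields so a
# malformed line is reported with its line number.

#' Read a PDB file into a StructureModel
#'
#' ATOM records only; HETATM and waters are skipped. Alternate locations are
#' collapsed per (chain, resseq, icode, name): the highest-occupancy altloc is
#' kept, ties going to the first in file order. Residue numbering and
#' insertion codes are taken verbatim from the file.
#'
#' @param path PDB file with ATOM/TER/END records.
#' @return a [structure_model()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  atoms <- data.frame(
    serial = at$eleno, name = at$elety,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resname = at$resid, chain = ifelse(is.na(at$chain), " ", at$chain),
    resseq = at$resno, icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    element = pdb_element(at$elesy, at$elety),
    stringsAsFactors = FALSE)
  atoms <- collapse_altlocs(atoms)
  structure_model(atoms, source = path)
}

# Cheap fixed-width validation so parse errors carry a line number.
#' @keywords internal
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^(ATOM  |HETATM)", lines)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB line ", i, " (shorter than coordinate block)")
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("malformed PDB line ", i, " (non-numeric coordinates)")
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))))
      stop("malformed PDB line ", i, " (non-numeric residue number)")
  }
  invisible(TRUE)
}

#' @keywords internal
pdb_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  # fall back to the first letter of the atom name (greek-position remainder
  # stripped); good enough for protein heavy atoms
  el[miss] <- substr(gsub("[^A-Za-z].*", "", trimws(elety[miss])), 1, 1)
  el
}

#' @keywords internal
collapse_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
  if (!anyDuplicated(key)) {
    atoms$altloc <- ""
    return(atoms)
  }
  keep <- logical(nrow(atoms))
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) > 1 && anyDuplicated(atoms$altloc[rows]))
      stop("duplicated atom (chain, resseq, icode, name, altloc): ", k)
    keep[rows[which.max(atoms$occupancy[rows])]] <- TRUE
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  atoms
}

#' Write a StructureModel as a PDB file
#'
#' Coordinates are written at the format's 3-decimal precision; chains are
#' separated by TER records.
#'
#' @param model a `StructureModel`.
#' @param path output file.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atom_xyz(at))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resseq, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = at$chain, insert = ifelse(at$icode == "", NA, at$icode),
                   o = at$occupancy, b = at$bfactor, elesy = at$element)
  invisible(path)
}
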