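# Quantitative structure comparison: Kabsch superposition and selection
# RMSD, named-atom displacement, Shrake-Rupley SASA and buried surface area,
# polar/hydrophobic contact counting, and phi/psi-based 3_10-helix
# classification.

#' Atom selection descriptor
#'
#' @param chain chain id(s).
#' @param resseq optional residue numbers (vector or range).
#' @param atoms optional atom names; `backbone = TRUE` selects N, CA, C, O.
#' @param backbone logical shortcut.
#' @return list of class `atom_selection`.
#' @export
sel <- function(chain = NULL, resseq = NULL, atoms = NULL, backbone = FALSE) {
  structure(list(chain = chain, resseq = resseq, atoms = atoms,
                 backbone = backbone), class = "atom_selection")
}

#' @keywords internal
apply_selection <- function(model, s) {
  if (is.null(s)) return(model$atoms)
  select_atoms(model, chain = s$chain, resseq = s$resseq,
               atom_names = s$atoms, backbone = s$backbone)
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid transform (proper rotation + translation) minimizing the
#' RMSD of `coords_move` onto `coords_ref`.
#'
#' @param coords_move,coords_ref n x 3 matrices, n >= 3, matched rows.
#' @return list of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd`. The transform maps a point x to
#'   `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(coords_move, coords_ref) {
  if (nrow(coords_move) != nrow(coords_ref))
    stop("coordinate sets differ in size: ", nrow(coords_move), " vs ",
         nrow(coords_ref))
  if (nrow(coords_move) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(coords_move); cr <- colMeans(coords_ref)
  A <- sweep(coords_move, 2, cm); B <- sweep(coords_ref, 2, cr)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd), class = "superposition")
}

#' @keywords internal
apply_superposition <- function(sp, coords) {
  sweep(coords %*% t(sp$rotation), 2, sp$translation, `+`)
}

# Pair atoms of two selections by (resseq, atom name); unpairable atoms are
# dropped with a warning.
#' @keywords internal
pair_atoms <- function(atomsA, atomsB, warn = TRUE) {
  keyA <- paste(atomsA$resseq, atomsA$name)
  keyB <- paste(atomsB$resseq, atomsB$name)
  common <- intersect(keyA, keyB)
  if (warn && (length(common) < length(keyA) || length(common) < length(keyB)))
    warning(length(keyA) + length(keyB) - 2 * length(common),
            " unpairable atom(s) dropped")
  list(A = atomsA[match(common, keyA), , drop = FALSE],
       B = atomsB[match(common, keyB), , drop = FALSE])
}

#' RMSD of a measured selection after superposing on a frame selection
#'
#' Superposes `structB` onto `structA` using the paired atoms of
#' `frame_selection`, then reports the RMSD over `measure_selection`
#' without refitting.
#'
#' @param structA,structB `StructureModel`s.
#' @param frame_selection,measure_selection [sel()] descriptors.
#' @param atom_set `"backbone"` (N, CA, C, O) or `"all-atom"` filter applied
#'   to the measure selection.
#' @return RMSD in Angstrom.
#' @export
selection_rmsd <- function(structA, structB, frame_selection,
                           measure_selection, atom_set = c("backbone",
                                                           "all-atom")) {
  atom_set <- match.arg(atom_set)
  fr <- pair_atoms(apply_selection(structA, frame_selection),
                   apply_selection(structB, frame_selection))
  if (nrow(fr$A) == 0) stop("empty frame pairing")
  sp <- kabsch_superpose(atom_xyz(fr$B), atom_xyz(fr$A))
  mA <- apply_selection(structA, measure_selection)
  mB <- apply_selection(structB, measure_selection)
  if (atom_set == "backbone") {
    mA <- mA[mA$name %in% BACKBONE_ATOMS, , drop = FALSE]
    mB <- mB[mB$name %in% BACKBONE_ATOMS, , drop = FALSE]
  }
  pm <- pair_atoms(mA, mB)
  if (nrow(pm$A) == 0) stop("empty measure pairing")
  moved <- apply_superposition(sp, atom_xyz(pm$B))
  sqrt(mean(rowSums((moved - atom_xyz(pm$A))^2)))
}

#' Displacement of one named atom between two structures
#'
#' Distance between the atom's positions after superposing `structB` onto
#' `structA` on the frame selection.
#'
#' @param structA,structB `StructureModel`s.
#' @param frame_selection [sel()] descriptor for the fit.
#' @param chain,resseq,atom identify the atom (e.g. Arg151 CA).
#' @return distance in Angstrom.
#' @export
atom_displacement <- function(structA, structB, frame_selection,
                              chain, resseq, atom = "CA") {
  fr <- pair_atoms(apply_selection(structA, frame_selection),
                   apply_selection(structB, frame_selection))
  sp <- kabsch_superpose(atom_xyz(fr$B), atom_xyz(fr$A))
  getA <- select_atoms(structA, chain = chain, resseq = resseq,
                       atom_names = atom)
  getB <- select_atoms(structB, chain = chain, resseq = resseq,
                       atom_names = atom)
  if (nrow(getA) != 1 || nrow(getB) != 1)
    stop("atom ", chain, ":", resseq, ":", atom,
         " not uniquely present in both structures")
  moved <- apply_superposition(sp, atom_xyz(getB))
  sqrt(sum((moved - atom_xyz(getA))^2))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numeric SASA per atom with a deterministic spherical Fibonacci point set;
#' hydrogens are not modelled (crystal structures lack them).
#'
#' @param x a `StructureModel` or atom data.frame.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return list of class `sasa_result`: `area` (per atom), `total`, `probe`,
#'   `n_points`.
#' @export
sasa <- function(x, probe = 1.4, n_points = 960L) {
  atoms <- if (inherits(x, "StructureModel")) x$atoms else x
  rad <- vdw_radius(atoms$element)
  area <- cpp_sasa(atom_xyz(atoms), rad, probe, fibonacci_sphere(n_points))
  structure(list(area = area, total = sum(area), probe = probe,
                 n_points = n_points), class = "sasa_result")
}

#' Buried surface area between two selections
#'
#' SASA(A alone) + SASA(B alone) - SASA(A and B together); the standard
#' two-sided interface area.
#'
#' @param model a `StructureModel`.
#' @param selA,selB disjoint [sel()] descriptors.
#' @inheritParams sasa
#' @return buried area in square Angstrom.
#' @export
buried_surface_area <- function(model, selA, selB, probe = 1.4,
                                n_points = 960L) {
  A <- apply_selection(model, selA)
  B <- apply_selection(model, selB)
  keyA <- paste(A$chain, A$resseq, A$icode, A$name)
  keyB <- paste(B$chain, B$resseq, B$icode, B$name)
  if (length(intersect(keyA, keyB)) > 0)
    stop("selections overlap")
  sasa(A, probe, n_points)$total + sasa(B, probe, n_points)$total -
    sasa(rbind(A, B), probe, n_points)$total
}

HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP",
                     "GLY")

#' Polar and hydrophobic contacts between two selections
#'
#' Polar: N/O to N/O pairs within `polar_cutoff`. Hydrophobic: carbon-carbon
#' pairs within `hydrophobic_cutoff` where each carbon is a side-chain atom
#' or belongs to an apolar residue.
#'
#' @param model a `StructureModel`.
#' @param selA,selB disjoint [sel()] descriptors.
#' @param polar_cutoff,hydrophobic_cutoff distances in Angstrom (defaults
#'   3.5 and 4.5).
#' @return data.frame: `type`, `chainA`, `resseqA`, `atomA`, `chainB`,
#'   `resseqB`, `atomB`, `distance`.
#' @export
contacts <- function(model, selA, selB, polar_cutoff = 3.5,
                     hydrophobic_cutoff = 4.5) {
  A <- apply_selection(model, selA)
  B <- apply_selection(model, selB)
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(type = character(), chainA = character(),
                      resseqA = integer(), atomA = character(),
                      chainB = character(), resseqB = integer(),
                      atomB = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  d <- sqrt(outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 +
              outer(A$z, B$z, "-")^2)
  polA <- toupper(A$element) %in% c("N", "O")
  polB <- toupper(B$element) %in% c("N", "O")
  hydA <- toupper(A$element) == "C" &
    (!(A$name %in% BACKBONE_ATOMS) | A$resname %in% HYDROPHOBIC_RES)
  hydB <- toupper(B$element) == "C" &
    (!(B$name %in% BACKBONE_ATOMS) | B$resname %in% HYDROPHOBIC_RES)
  hit_p <- which(outer(polA, polB, "&") & d <= polar_cutoff, arr.ind = TRUE)
  hit_h <- which(outer(hydA, hydB, "&") & d <= hydrophobic_cutoff,
                 arr.ind = TRUE)
  mk <- function(hits, type) {
    if (nrow(hits) == 0) return(NULL)
    data.frame(type = type,
               chainA = A$chain[hits[, 1]], resseqA = A$resseq[hits[, 1]],
               atomA = A$name[hits[, 1]],
               chainB = B$chain[hits[, 2]], resseqB = B$resseq[hits[, 2]],
               atomB = B$name[hits[, 2]], distance = d[hits],
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(hit_p, "polar"), mk(hit_h, "hydrophobic"))
  if (is.null(out))
    out <- data.frame(type = character(), chainA = character(),
                      resseqA = integer(), atomA = character(),
                      chainB = character(), resseqB = integer(),
                      atomB = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Backbone phi/psi dihedrals of a chain
#'
#' @param model a `StructureModel`.
#' @param chain chain id.
#' @return data.frame: `resseq`, `phi`, `psi` (degrees; NA where undefined
#'   at termini or for missing backbone atoms).
#' @export
phi_psi <- function(model, chain) {
  res <- model_residues(model, chain)
  at <- select_atoms(model, chain = chain)
  get <- function(i, nm) {
    row <- at[at$resseq == res$resseq[i] & at$icode == res$icode[i] &
                at$name == nm, , drop = FALSE]
    if (nrow(row) != 1) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  n <- nrow(res)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- get(i, "N"); CA <- get(i, "CA"); C <- get(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1) {
      Cp <- get(i - 1, "C")
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, N, CA, C)
    }
    if (i < n) {
      Nn <- get(i + 1, "N")
      if (!is.null(Nn)) psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  data.frame(resseq = res$resseq, phi = phi, psi = psi)
}

#' Classify residues and find 3_10-helical spans
#'
#' A residue is 3_10-helical if phi is in [-90, -40] and psi in [-45, 0]
#' degrees; alpha and beta classes use standard Ramachandran windows; spans
#' are maximal runs of at least `run_length` 3_10 residues.
#'
#' @param records data.frame from [phi_psi()].
#' @param run_length minimum run length (default 3).
#' @return list with `class` (per residue: `3_10`, `alpha`, `beta`, `other`,
#'   or NA where dihedrals are undefined) and `spans` (data.frame `from`,
#'   `to` in residue numbers).
#' @export
classify_310 <- function(records, run_length = 3L) {
  cls <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    phi <- records$phi[i]; psi <- records$psi[i]
    if (is.na(phi) || is.na(psi)) next
    cls[i] <- if (phi >= -90 && phi <= -40 && psi >= -45 && psi <= 0) "3_10"
    else if (phi >= -100 && phi <= -30 && psi >= -67 && psi < -45) "alpha"
    else if (phi < -45 && (psi > 90 || psi < -150)) "beta"
    else "other"
  }
  r <- rle(cls == "3_10" & !is.na(cls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= run_length
  spans <- data.frame(from = records$resseq[starts[keep]],
                      to = records$resseq[ends[keep]])
  list(class = cls, spans = spans)
}
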