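# Simplified physics energy model used for threading and repacking. Four
# terms: softened Lennard-Jones, a distance-window hydrogen-bond bonus, a
# screened Coulomb with distance-dependent dielectric, and a burial penalty
# for polar atoms. This is an own documented score, not any published force
# field; every assertion built on it is about orderings and signs, never
# absolute values.

#' Construct the energy function (term weights and atom parameters)
#'
#' @param w_lj,w_hb,w_coul,w_solv term weights (model energy units).
#' @param clash_cap per-pair Lennard-Jones cap; a pair hitting the cap flags
#'   the model as hard-clashed.
#' @return list of class `energy_function`.
#' @export
energy_function <- function(w_lj = 1.0, w_hb = 1.0, w_coul = 1.0,
                            w_solv = 0.25, clash_cap = 100) {
  structure(list(w_lj = w_lj, w_hb = w_hb, w_coul = w_coul, w_solv = w_solv,
                 clash_cap = clash_cap,
                 eps = c(C = 0.10, N = 0.15, O = 0.15, S = 0.20,
                         P = 0.20, SE = 0.20)),
            class = "energy_function")
}

# Formal charges (elementary units) on side-chain atoms of ionizable
# residues; everything else neutral.
#' @keywords internal
atom_charge <- function(resname, name) {
  q <- numeric(length(name))
  q[resname == "ARG" & name %in% c("NH1", "NH2")] <- 0.5
  q[resname == "LYS" & name == "NZ"] <- 1.0
  q[resname == "ASP" & name %in% c("OD1", "OD2")] <- -0.5
  q[resname == "GLU" & name %in% c("OE1", "OE2")] <- -0.5
  q
}

#' Per-atom parameter table for the energy kernels
#'
#' @param atoms atom data.frame (StructureModel columns).
#' @return list of parallel vectors: `xyz`, `rad`, `eps`, `q`, `don`, `acc`,
#'   `polar`, `backbone`, `residx`, `chainidx`.
#' @keywords internal
atom_params <- function(atoms, efn = energy_function()) {
  el <- toupper(atoms$element)
  rad <- vdw_radius(el)
  eps <- efn$eps[el]
  if (anyNA(eps)) stop("no well depth for element(s): ",
                       paste(unique(el[is.na(eps)]), collapse = ", "))
  don <- el == "N" | atoms$name %in% c("OG", "OG1", "OH")
  acc <- el == "O"
  polar <- el %in% c("N", "O")
  reskey <- paste(atoms$chain, atoms$resseq, atoms$icode)
  residx <- as.integer(factor(reskey, levels = unique(reskey)))
  chainidx <- as.integer(factor(atoms$chain, levels = unique(atoms$chain)))
  list(xyz = atom_xyz(atoms), rad = unname(rad), eps = unname(eps),
       q = atom_charge(atoms$resname, atoms$name),
       don = don, acc = acc, polar = polar,
       backbone = atoms$name %in% BACKBONE_ATOMS,
       residx = residx, chainidx = chainidx)
}

#' Total energy of an atom set under the full model
#'
#' Pairwise terms with bonded exclusions (same residue; backbone-backbone in
#' chain-adjacent residues) plus the polar burial penalty.
#'
#' @param atoms atom data.frame.
#' @param efn an [energy_function()].
#' @return list with `total`, `pair`, `solv`, `solv_per_atom`, `clashed`.
#' @export
total_energy <- function(atoms, efn = energy_function()) {
  p <- atom_params(atoms, efn)
  cpp_energy_full(p$xyz, p$rad, p$eps, p$q, p$don, p$acc, p$polar,
                  p$residx, p$chainidx, p$backbone,
                  efn$w_lj, efn$w_hb, efn$w_coul, efn$w_solv, efn$clash_cap)
}

#' Interaction energy between two atom sets (pair terms only, no exclusions)
#'
#' @param atomsA,atomsB atom data.frames (disjoint sets).
#' @param efn an [energy_function()].
#' @return list with `total`, `per_atom` (per atom of `atomsA`), `clashed`.
#' @export
cross_energy <- function(atomsA, atomsB, efn = energy_function()) {
  pa <- atom_params(atomsA, efn); pb <- atom_params(atomsB, efn)
  cpp_pair_energy(pa$xyz, pa$rad, pa$eps, pa$q, pa$don, pa$acc,
                  pb$xyz, pb$rad, pb$eps, pb$q, pb$don, pb$acc,
                  efn$w_lj, efn$w_hb, efn$w_coul, efn$clash_cap)
}

#' Deterministic unit-sphere point set (spherical Fibonacci lattice)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
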