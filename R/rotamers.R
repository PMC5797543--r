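# Side-chain internal-coordinate topology for the 20 standard residues
# (heavy atoms only), a compact backbone-independent rotamer library, and
# builders for side chains and ideal backbones. The library is deliberately
# small (<= 9 rotamers per type) for reproducibility; a richer library can be
# supplied anywhere a `rotlib` argument is accepted.

# Each topology row: atom, refs (a, b, c; the new atom bonds to c), bond
# length, bond angle b-c-new, and the torsion a-b-c-new given as chi index
# (0 = fixed) plus an offset in degrees.
#' @keywords internal
sidechain_topology <- function() {
  row <- function(atom, a, b, c, bond, angle, chi, offset = 0)
    list(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
         chi = chi, offset = offset)
  CB <- row("CB", "C", "N", "CA", 1.53, 110.5, 0, 122.8)
  list(
    GLY = list(),
    ALA = list(CB),
    SER = list(CB, row("OG",  "N", "CA", "CB", 1.42, 110.8, 1)),
    CYS = list(CB, row("SG",  "N", "CA", "CB", 1.81, 113.8, 1)),
    THR = list(CB, row("OG1", "N", "CA", "CB", 1.43, 109.6, 1),
               row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -120)),
    VAL = list(CB, row("CG1", "N", "CA", "CB", 1.53, 110.8, 1),
               row("CG2", "N", "CA", "CB", 1.53, 110.8, 1, 122.3)),
    LEU = list(CB, row("CG",  "N", "CA", "CB", 1.53, 116.3, 1),
               row("CD1", "CA", "CB", "CG", 1.52, 110.7, 2),
               row("CD2", "CA", "CB", "CG", 1.52, 110.7, 2, 122.6)),
    ILE = list(CB, row("CG1", "N", "CA", "CB", 1.53, 110.4, 1),
               row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -122.3),
               row("CD1", "CA", "CB", "CG1", 1.52, 113.9, 2)),
    MET = list(CB, row("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
               row("SD",  "CA", "CB", "CG", 1.80, 112.7, 2),
               row("CE",  "CB", "CG", "SD", 1.79, 100.9, 3)),
    PRO = list(CB, row("CG",  "N", "CA", "CB", 1.50, 104.5, 1),
               row("CD",  "CA", "CB", "CG", 1.51, 106.1, 2)),
    PHE = list(CB, row("CG",  "N", "CA", "CB", 1.50, 113.8, 1),
               row("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
               row("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
               row("CE1", "CB", "CG", "CD1", 1.39, 120.8, 0, 180),
               row("CE2", "CB", "CG", "CD2", 1.39, 120.8, 0, 180),
               row("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0)),
    TYR = list(CB, row("CG",  "N", "CA", "CB", 1.50, 113.8, 1),
               row("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
               row("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
               row("CE1", "CB", "CG", "CD1", 1.39, 120.8, 0, 180),
               row("CE2", "CB", "CG", "CD2", 1.39, 120.8, 0, 180),
               row("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
               row("OH",  "CD1", "CE1", "CZ", 1.38, 119.9, 0, 180)),
    TRP = list(CB, row("CG",  "N", "CA", "CB", 1.50, 113.6, 1),
               row("CD1", "CA", "CB", "CG", 1.37, 126.9, 2),
               row("CD2", "CA", "CB", "CG", 1.43, 126.7, 2, 180),
               row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0, 180),
               row("CE2", "CG", "CD1", "NE1", 1.37, 109.0, 0, 0),
               row("CE3", "CD1", "CG", "CD2", 1.40, 133.9, 0, 180),
               row("CZ2", "CD1", "NE1", "CE2", 1.40, 130.4, 0, 180),
               row("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, 0, 180),
               row("CH2", "NE1", "CE2", "CZ2", 1.37, 117.5, 0, 180)),
    ASP = list(CB, row("CG",  "N", "CA", "CB", 1.52, 113.1, 1),
               row("OD1", "CA", "CB", "CG", 1.25, 118.2, 2),
               row("OD2", "CA", "CB", "CG", 1.25, 118.2, 2, 180)),
    ASN = list(CB, row("CG",  "N", "CA", "CB", 1.52, 112.7, 1),
               row("OD1", "CA", "CB", "CG", 1.23, 120.8, 2),
               row("ND2", "CA", "CB", "CG", 1.33, 116.5, 2, 180)),
    GLU = list(CB, row("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
               row("CD",  "CA", "CB", "CG", 1.52, 112.6, 2),
               row("OE1", "CB", "CG", "CD", 1.25, 118.3, 3),
               row("OE2", "CB", "CG", "CD", 1.25, 118.3, 3, 180)),
    GLN = list(CB, row("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
               row("CD",  "CA", "CB", "CG", 1.52, 112.6, 2),
               row("OE1", "CB", "CG", "CD", 1.23, 120.8, 3),
               row("NE2", "CB", "CG", "CD", 1.33, 116.5, 3, 180)),
    LYS = list(CB, row("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
               row("CD",  "CA", "CB", "CG", 1.52, 111.3, 2),
               row("CE",  "CB", "CG", "CD", 1.52, 111.3, 3),
               row("NZ",  "CG", "CD", "CE", 1.49, 111.9, 4)),
    ARG = list(CB, row("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
               row("CD",  "CA", "CB", "CG", 1.52, 111.3, 2),
               row("NE",  "CB", "CG", "CD", 1.46, 111.5, 3),
               row("CZ",  "CG", "CD", "NE", 1.33, 124.2, 4),
               row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0, 0),
               row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0, 180)),
    HIS = list(CB, row("CG",  "N", "CA", "CB", 1.50, 113.8, 1),
               row("ND1", "CA", "CB", "CG", 1.38, 122.7, 2),
               row("CD2", "CA", "CB", "CG", 1.36, 131.0, 2, 180),
               row("CE1", "CB", "CG", "ND1", 1.32, 109.3, 0, 180),
               row("NE2", "CG", "ND1", "CE1", 1.34, 111.0, 0, 0)))
}

#' @keywords internal
SIDECHAIN_TOPOLOGY <- sidechain_topology()

#' Number of chi angles of a residue type
#' @param resname three-letter residue code.
#' @export
n_chi <- function(resname) {
  topo <- SIDECHAIN_TOPOLOGY[[toupper(resname)]]
  if (is.null(topo)) stop("unknown residue type: ", resname)
  if (length(topo) == 0) return(0L)
  max(vapply(topo, function(r) r$chi, numeric(1)))
}

#' Bundled backbone-independent rotamer library
#'
#' A compact library: per residue type a matrix of chi angles (degrees, one
#' row per rotamer) and prior probabilities summing to 1. Chi counts match
#' the residue topology.
#'
#' @return named list; each element has `chis` (matrix) and `prob` (vector).
#' @export
rotamer_library <- function() {
  rot <- function(prob, ...) {
    chis <- do.call(rbind, list(...))
    list(chis = chis, prob = prob / sum(prob))
  }
  single <- list(chis = matrix(numeric(0), nrow = 1, ncol = 0), prob = 1)
  g <- c(-60, 180, 60)  # gauche-, trans, gauche+
  list(
    GLY = single, ALA = single,
    SER = rot(c(.48, .29, .23), g[1], g[2], g[3]),
    CYS = rot(c(.50, .30, .20), g[1], g[2], g[3]),
    THR = rot(c(.49, .44, .07), g[1], g[3], g[2]),
    VAL = rot(c(.73, .20, .07), 175, -60, 64),
    LEU = rot(c(.59, .29, .08, .04), c(-65, 175), c(-175, 65), c(-85, 65),
              c(-60, -65)),
    ILE = rot(c(.60, .15, .13, .12), c(-65, 170), c(-65, -60), c(-177, 165),
              c(62, 170)),
    MET = rot(c(.35, .25, .20, .20), c(-65, -65, -70), c(-65, 180, 75),
              c(-175, 175, 75), c(-65, 180, 180)),
    PRO = rot(c(.55, .45), c(30, -35), c(-25, 35)),
    PHE = rot(c(.50, .33, .17), c(-65, 90), c(180, 80), c(60, 90)),
    TYR = rot(c(.50, .33, .17), c(-65, 90), c(180, 80), c(60, 90)),
    TRP = rot(c(.30, .25, .20, .15, .10), c(-65, 95), c(-65, -90),
              c(180, 110), c(180, -105), c(60, -90)),
    ASP = rot(c(.50, .33, .17), c(-65, -15), c(180, 15), c(60, -10)),
    ASN = rot(c(.45, .30, .15, .10), c(-65, -40), c(180, -40), c(-65, 120),
              c(60, -20)),
    GLU = rot(c(.35, .25, .20, .12, .08), c(-65, 180, -10), c(-65, -65, -40),
              c(180, 180, 0), c(180, 65, 10), c(60, 180, -10)),
    GLN = rot(c(.35, .25, .20, .12, .08), c(-65, 180, -25), c(-65, -65, -40),
              c(180, 180, 0), c(180, 65, 20), c(60, 180, -25)),
    LYS = rot(c(.30, .20, .15, .13, .12, .10),
              c(-65, 180, 180, 180), c(180, 180, 180, 180),
              c(-65, -65, 180, 180), c(-65, 180, -65, 180),
              c(180, 65, 180, 180), c(60, 180, 180, 180)),
    ARG = rot(c(.22, .18, .15, .12, .11, .09, .07, .06),
              c(-65, 180, 180, 180), c(-65, 180, 180, -85),
              c(180, 180, 180, 180), c(-65, -65, 180, 180),
              c(180, 180, -65, -85), c(-65, 180, -65, 180),
              c(180, 65, 65, 85), c(60, 180, 180, 180)),
    HIS = rot(c(.45, .30, .25), c(-65, -70), c(180, -80), c(60, 80)))
}

#' @keywords internal
ROTAMER_LIBRARY <- rotamer_library()

#' @keywords internal
validate_rotlib <- function(rotlib) {
  for (res in names(rotlib)) {
    x <- rotlib[[res]]
    if (abs(sum(x$prob) - 1) > 1e-6)
      stop("rotamer probabilities for ", res, " do not sum to 1")
    if (!is.null(SIDECHAIN_TOPOLOGY[[res]]) && ncol(x$chis) != n_chi(res))
      stop("chi count mismatch for ", res)
  }
  invisible(TRUE)
}

#' Build side-chain heavy atoms from backbone coordinates and chi angles
#'
#' @param resname three-letter residue type.
#' @param chis numeric chi angles in degrees (length [n_chi()]).
#' @param N,CA,C backbone xyz triples.
#' @return data.frame with `name`, `x`, `y`, `z`, `element` for every
#'   side-chain heavy atom (CB onward); zero rows for glycine.
#' @export
build_sidechain <- function(resname, chis, N, CA, C) {
  resname <- toupper(resname)
  topo <- SIDECHAIN_TOPOLOGY[[resname]]
  if (is.null(topo)) stop("unknown residue type: ", resname)
  if (length(topo) == 0)
    return(data.frame(name = character(), x = numeric(), y = numeric(),
                      z = numeric(), element = character(),
                      stringsAsFactors = FALSE))
  if (length(chis) != n_chi(resname))
    stop(resname, " needs ", n_chi(resname), " chi angle(s), got ",
         length(chis))
  pos <- list(N = N, CA = CA, C = C)
  out <- vector("list", length(topo))
  for (i in seq_along(topo)) {
    r <- topo[[i]]
    tor <- if (r$chi == 0) r$offset else chis[r$chi] + r$offset
    p <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]], r$bond, r$angle, tor)
    pos[[r$atom]] <- p
    out[[i]] <- data.frame(name = r$atom, x = p[1], y = p[2], z = p[3],
                           element = substr(r$atom, 1, 1),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Most probable rotamer of a residue type
#' @param resname three-letter code.
#' @param rotlib rotamer library (default bundled).
#' @return numeric chi vector (length 0 for Gly/Ala).
#' @export
best_rotamer <- function(resname, rotlib = ROTAMER_LIBRARY) {
  x <- rotlib[[toupper(resname)]]
  if (is.null(x)) stop("residue type missing from rotamer library: ", resname)
  x$chis[which.max(x$prob), ]
}

# Ideal backbone geometry constants.
BB_N_CA <- 1.458; BB_CA_C <- 1.525; BB_C_N <- 1.329; BB_C_O <- 1.231
BB_ANG_N_CA_C <- 111.2; BB_ANG_CA_C_N <- 116.2; BB_ANG_C_N_CA <- 121.7
BB_ANG_CA_C_O <- 120.5

#' Build an ideal-geometry backbone from phi/psi angles
#'
#' Plants residue 1 at the origin and grows the chain with ideal bond
#' lengths/angles and trans (omega = 180) peptide bonds. `phi[1]` and
#' `psi[length]` are ignored (undefined at termini but must be supplied).
#'
#' @param phi,psi numeric vectors (degrees), one entry per residue.
#' @return list of per-residue lists with `N`, `CA`, `C`, `O` xyz triples.
#' @export
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(BB_N_CA, 0, 0)
  ang <- BB_ANG_N_CA_C * pi / 180
  C <- CA + c(-BB_CA_C * cos(ang), BB_CA_C * sin(ang), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)[-1]) {
    prev <- res[[i - 1]]
    Ni <- place_atom(prev$N, prev$CA, prev$C, BB_C_N, BB_ANG_CA_C_N, psi[i - 1])
    CAi <- place_atom(prev$CA, prev$C, Ni, BB_N_CA, BB_ANG_C_N_CA, 180)
    Ci <- place_atom(prev$C, Ni, CAi, BB_CA_C, BB_ANG_N_CA_C, phi[i])
    res[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  for (i in seq_len(n)) {
    psi_i <- if (i < n) psi[i] else 180
    res[[i]]$O <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                             BB_C_O, BB_ANG_CA_C_O, psi_i + 180)
  }
  res
}
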