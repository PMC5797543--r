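# Small vector-geometry kernel: dihedrals, bond angles, and NeRF-style
# placement of an atom from internal coordinates (bond, angle, torsion).
# All angles in degrees, all distances in Angstrom.

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate (zero-length) vector in geometry")
  v / n
}

#' Dihedral angle of four points
#'
#' Signed torsion p1-p2-p3-p4 in degrees, in (-180, 180], IUPAC convention.
#' @param p1,p2,p3,p4 numeric xyz triples.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Bond angle of three points
#'
#' Angle at p2 in degrees.
#' @param p1,p2,p3 numeric xyz triples.
#' @export
bond_angle <- function(p1, p2, p3) {
  v1 <- unit3(p1 - p2); v2 <- unit3(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Place an atom from internal coordinates
#'
#' Returns the position `d` bonded to `c` such that |c-d| = `bond`,
#' the angle b-c-d equals `angle` and the torsion a-b-c-d equals `torsion`
#' (as measured by [dihedral_angle()]).
#'
#' @param a,b,c xyz triples of the three reference atoms.
#' @param bond bond length (Angstrom).
#' @param angle bond angle b-c-d (degrees).
#' @param torsion dihedral a-b-c-d (degrees).
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
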