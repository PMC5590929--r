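# Low-level 3D geometry: internal-coordinate atom placement and dihedrals.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Given three reference atoms `a`, `b`, `c`, returns the position `d` such
#' that |c-d| = `length`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `torsion` (natural extension reference frame).
#'
#' @param a,b,c Numeric length-3 coordinates of the three reference atoms.
#' @param length Bond length c-d in Angstroms.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Numeric length-3 coordinate.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}
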