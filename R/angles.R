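# Elementary angular and vector geometry used by both reaction coordinates.
# All angles are degrees in the canonical wrapped range [-180, 180); the
# trans/antiperiplanar arrangement is represented as -180 so that every
# physically distinct angle has exactly one representation in histograms.

#' Wrap an angle into the canonical range
#'
#' Maps any finite angle (degrees) onto `[-180, 180)`; `+180` and `-180`
#' denote the same arrangement and both map to `-180`.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each value in `[-180, 180)`.
#' @examples
#' wrap_angle(c(190, -180, 360, 181))
#' @export
wrap_angle <- function(x) {
  stopifnot(is.numeric(x))
  if (any(!is.finite(x))) stop("wrap_angle: non-finite angle")
  ((x + 180) %% 360) - 180
}

#' Minimal-image signed difference between two angles
#'
#' `angle_diff(a, b)` is the wrapped representation of `a - b`, i.e. the
#' signed displacement of `a` from `b` along the shorter arc (magnitude
#' at most 180 degrees).
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed differences in degrees, in `[-180, 180)`.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Signed dihedral angle of four points
#'
#' Computes the IUPAC signed dihedral defined by four consecutive points:
#' the angle between the plane (a, b, c) and the plane (b, c, d), with the
#' sign given by the right-hand rule about the b -> c axis. The eclipsed
#' (cis) arrangement is 0 and the antiperiplanar (trans) arrangement is
#' reported as -180, the wrapped representation of 180.
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return The dihedral in degrees, in `[-180, 180)`.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 1))   # cis: 0
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))  # trans: -180
#' @export
dihedral <- function(a, b, c, d) {
  for (p in list(a, b, c, d)) {
    if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p))) {
      stop("dihedral: each point must be a finite numeric 3-vector")
    }
  }
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10) stop("dihedral: degenerate geometry, points b and c coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10) {
    stop("dihedral: degenerate geometry, points a, b, c are collinear")
  }
  if (sqrt(sum(n2^2)) < 1e-10) {
    stop("dihedral: degenerate geometry, points b, c, d are collinear")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / nb2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Mass-weighted centre of a set of atoms
#'
#' @param masses Positive numeric vector of atomic masses (amu).
#' @param positions Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom), or a single 3-vector.
#' @return The centre of mass as a numeric 3-vector.
#' @examples
#' center_of_mass(c(12, 1), rbind(c(0, 0, 0), c(13, 0, 0)))  # c(1, 0, 0)
#' @export
center_of_mass <- function(masses, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L)
  if (length(masses) == 0L || nrow(positions) == 0L) {
    stop("center_of_mass: empty atom selection")
  }
  if (length(masses) != nrow(positions)) {
    stop("center_of_mass: masses and positions disagree in length")
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("center_of_mass: masses must be finite and > 0")
  }
  as.numeric(colSums(positions * masses) / sum(masses))
}
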