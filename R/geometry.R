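# Shared 3D geometry: dihedrals, internal-coordinate atom placement,
# ideal C-beta construction.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking along the central bond `b -> c`, the angle
#' is positive when the far bond `c -> d` is rotated clockwise from the near
#' bond `b -> a`. Result in degrees in `(-180, 180]`.
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  ang <- atan2(-sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural-extension-reference-frame placement: position atom D given atoms
# A, B, C, the bond length |C-D|, the angle B-C-D (deg) and the torsion
# A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Ideal C-beta position from backbone N, CA, C (L-amino-acid chirality,
# |CA-CB| ~ 1.53 A). Used both by the fixture builder and as the pseudo-CB
# for glycine in half-sphere contact counting.
ideal_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * cc)
}

# random rigid-body motion, for invariance tests and API completeness
rigid_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, "+")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
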