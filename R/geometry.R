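## Ideal backbone geometry.
##
## The peptide-bond constants (C-N length, CA-C-N and C-N-CA angles) are the
## ring-closure values used throughout: every peptide bond in a macrocycle is
## built with the same geometry as the closure bond, so closed rings are
## indistinguishable from rings that were never cut.  The remaining constants
## are standard amide-geometry values (Engh-Huber-like).  All angles degrees,
## all lengths Angstrom.  Never mutated at runtime.
.ideal <- list(
  b_n_ca  = 1.458,
  b_ca_c  = 1.524,
  b_c_n   = 1.328685,
  b_c_o   = 1.231,
  b_n_h   = 1.010,
  b_n_cn  = 1.455,
  b_ca_cb = 1.530,
  a_n_ca_c  = 111.2,
  a_ca_c_n  = 116.199993,
  a_c_n_ca  = 121.69997,
  a_ca_c_o  = 120.8,
  a_n_ca_cb = 110.5,
  t_c_n_ca_cb = 122.6,   # improper C-N-CA-CB, +/- by chirality
  closure = list(bondlength = 1.328685, angle1 = 121.69997,
                 angle2 = 116.199993, omega = 180.0)
)

#' Ideal backbone geometry table
#'
#' Returns the configuration constants used when building backbones from
#' internal coordinates: bond lengths, bond angles, dependent-atom placement
#' parameters and the ring-closure bond geometry (`$closure`).
#'
#' @return A named list of geometry constants.
#' @export
ideal_geometry <- function() .ideal

.deg2rad <- pi / 180

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return Angles wrapped to the canonical torsion interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180] <- y[y <= -180] + 360
  y
}

## angular distance |a - b| on the circle, degrees in [0, 180]
ang_dist <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  d
}

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at p2 (degrees)
#' @param p1,p2,p3 coordinate vectors (length 3).
#' @return Angle p1-p2-p3 in degrees.
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) / .deg2rad
}

#' Dihedral angle (degrees, IUPAC sign convention)
#'
#' @param p1,p2,p3,p4 coordinate vectors (length 3).
#' @return Signed dihedral in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unitv(b2))
  wrap_angle(atan2(y, x) / .deg2rad)
}

## Natural-extension reference frame placement: returns D with |C-D| = bond,
## angle(B,C,D) = ang (deg) and dihedral(A,B,C,D) = tor (deg).
nerf_place <- function(A, B, C, bond, ang, tor) {
  ang <- ang * .deg2rad
  tor <- tor * .deg2rad
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

## Rodrigues rotation of vector v about unit axis e by theta degrees.
rotate_about <- function(v, e, theta) {
  th <- theta * .deg2rad
  v * cos(th) + cross3(e, v) * sin(th) + e * sum(e * v) * (1 - cos(th))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Proper-rotation superposition of point set `P` onto `Q` (both m x 3).
#' Reflections are never introduced; mirror comparisons must reflect the
#' coordinates explicitly beforehand.
#'
#' @param P,Q m x 3 coordinate matrices with matching rows.
#' @return List with `rmsd`, rotation matrix `R` and translation so that
#'   `P %*% R + t` superposes onto `Q`.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  Pr <- P0 %*% R
  rmsd <- sqrt(sum((Pr - Q0)^2) / nrow(P))
  list(rmsd = rmsd, R = R, t = cq - cp %*% R)
}
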