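# Vectorised 3-vector geometry on n x 3 matrices (rows = frames or points).

as_mat3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else x
}

vnorm3 <- function(m) sqrt(rowSums(m * m))

unitv3 <- function(m) m / vnorm3(m)

vdot3 <- function(a, b) rowSums(a * b)

vcross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# angle p1-p2-p3 in degrees; degenerate (zero-length arm) -> NA
angle_deg <- function(p1, p2, p3) {
  p1 <- as_mat3(p1); p2 <- as_mat3(p2); p3 <- as_mat3(p3)
  u <- p1 - p2; v <- p3 - p2
  nu <- vnorm3(u); nv <- vnorm3(v)
  cosang <- vdot3(u, v) / (nu * nv)
  cosang[nu == 0 | nv == 0] <- NA_real_
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# signed dihedral p1-p2-p3-p4 in degrees, IUPAC convention
# (positive clockwise looking from p2 towards p3), wrapped to (-180, 180]
dihedral_deg <- function(p1, p2, p3, p4) {
  p1 <- as_mat3(p1); p2 <- as_mat3(p2); p3 <- as_mat3(p3); p4 <- as_mat3(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross3(b1, b2); n2 <- vcross3(b2, b3)
  m1 <- vcross3(n1, unitv3(b2))
  wrap_deg(atan2(vdot3(m1, n2), vdot3(n1, n2)) * 180 / pi)
}

# wrap angles (degrees) to (-180, 180]
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Place point D given A, B, C with |CD| = r, angle(B,C,D) = theta (deg) and
# dihedral(A,B,C,D) = phi (deg).  All of A,B,C may be n x 3; r/theta/phi
# scalars or length-n.  Self-consistent with angle_deg()/dihedral_deg().
nerf_place <- function(A, B, C, r, theta, phi) {
  A <- as_mat3(A); B <- as_mat3(B); C <- as_mat3(C)
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- unitv3(C - B)
  n <- unitv3(vcross3(B - A, bc))
  m <- vcross3(n, bc)
  d1 <- -r * cos(th)
  d2 <- r * sin(th) * cos(ph)
  d3 <- -r * sin(th) * sin(ph)
  C + bc * d1 + m * d2 + n * d3
}

# Triangle with side lengths d12, d23, d13 placed in the z = 0 plane:
# p1 at the origin, p2 on +x, p3 with positive y.  Vectorised over frames.
# Violation of the triangle inequality raises an error.
place_triangle <- function(d12, d23, d13) {
  x <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y2 <- d13^2 - x^2
  if (any(y2 <= 0))
    stop("ring edge lengths violate the triangle inequality (",
         "d12 = ", d12[[1L]], ", d23 = ", d23[[1L]], ", d13 = ", d13[[1L]], ")")
  n <- max(length(d12), length(d23), length(d13))
  zero <- numeric(n)
  list(p1 = cbind(zero, zero, zero),
       p2 = cbind(d12 + zero, zero, zero),
       p3 = cbind(x + zero, sqrt(y2) + zero, zero))
}

# rotation matrix about a unit axis by angle (degrees)
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  c <- cos(a); s <- sin(a)
  outer(u, u) * (1 - c) + diag(3) * c +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L) * s
}
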