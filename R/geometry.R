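# Small vector-geometry helpers (angstrom / degrees).

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Rodrigues rotation matrix: right-handed rotation by `angle` degrees
# about unit axis `u`.
rotation_matrix <- function(u, angle) {
  u <- unitv(u)
  th <- rad(angle)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cu <- vnorm(u); cv <- vnorm(v)
  if (cu < 1e-9 || cv < 1e-9) stop("coincident points in angle", call. = FALSE)
  deg(acos(max(-1, min(1, sum(u * v) / (cu * cv)))))
}

# Signed dihedral A-B-C-D in (-180, 180]; positive when, sighting from B
# to C, the rotation carrying A onto D is counter-clockwise (sign of
# (n1 x n2) . u_BC with n1, n2 the plane normals).
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- crossv(b1, b2); n2 <- crossv(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: collinear atoms", call. = FALSE)
  u <- unitv(b2)
  x <- sum(n1 * n2)
  y <- sum(crossv(n1, n2) * u)
  ang <- deg(atan2(y, x))
  if (ang <= -180) ang + 360 else ang
}
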