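# Internal rigid-body and internal-coordinate geometry primitives.
# All coordinates are A x 3 matrices in nm.

# Optimal rotation R (3x3) such that X %*% R best fits Y in least squares.
# X and Y must already be centered. Proper rotation enforced (det = +1).
kabsch_rotation <- function(X, Y) {
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Superpose X onto Y using the atom rows in `idx` for the fit; the transform is
# applied to all rows of X. Returns the transformed matrix.
superpose_onto <- function(X, Y, idx = seq_len(nrow(X))) {
  cx <- colMeans(X[idx, , drop = FALSE])
  cy <- colMeans(Y[idx, , drop = FALSE])
  Xc <- sweep(X, 2, cx)
  R <- kabsch_rotation(sweep(X[idx, , drop = FALSE], 2, cx),
                       sweep(Y[idx, , drop = FALSE], 2, cy))
  sweep(Xc %*% R, 2, cy, `+`)
}

# Least-squares RMSD between two coordinate sets over rows `idx`,
# optionally after optimal superposition.
rmsd_pair <- function(X, Y, idx = seq_len(nrow(X)), fit = TRUE) {
  A <- X[idx, , drop = FALSE]
  B <- Y[idx, , drop = FALSE]
  if (fit) {
    A <- sweep(A, 2, colMeans(A))
    B <- sweep(B, 2, colMeans(B))
    A <- A %*% kabsch_rotation(A, B)
  }
  sqrt(sum((A - B)^2) / nrow(A))
}

radius_of_gyration <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sqrt(sum(Xc^2) / nrow(X))
}

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# Natural-extension-reference-frame atom placement: position a new atom D given
# the three preceding atoms A-B-C, the C-D bond length, the B-C-D angle and the
# A-B-C-D torsion (angle and torsion in degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Rotate rows `idx` of X about the axis through `origin` with direction `axis`
# by `theta` degrees (Rodrigues rotation).
rotate_about_axis <- function(X, idx, origin, axis, theta) {
  k <- unit(axis)
  th <- deg2rad(theta)
  P <- sweep(X[idx, , drop = FALSE], 2, origin)
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  X[idx, ] <- sweep(P %*% t(R), 2, origin, `+`)
  X
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators are pure functions of their
# spec.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
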