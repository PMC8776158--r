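# Independent oracle implementations kept deliberately separate from the
# package code paths they check.

# Dihedral via explicitly constructed plane normals: signed acos form,
# a different trigonometric path from the package's atan2 form.
oracle_dihedral <- function(coords, idx) {
  p <- coords[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- xp(b1, b2)
  n2 <- xp(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosphi <- max(-1, min(1, cosphi))
  s <- sign(sum(xp(n1, n2) * b2))
  ang <- s * acos(cosphi) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Random proper rotation built from QR (different construction from the
# package's quaternion sampler).
oracle_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_isometry <- function(s, rot = oracle_rotation(), trans = rnorm(3, 0, 5)) {
  s$coords <- s$coords %*% t(rot) +
    matrix(trans, nrow(s$coords), 3, byrow = TRUE)
  s
}

euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# Brute-force rigid-superposition RMSD: centroid-matched translation plus
# numerical optimization over Euler angles from many random starts.
oracle_superpose_rmsd <- function(pa, pb, n_starts = 30) {
  qa <- sweep(pa, 2, colMeans(pa))
  qb <- sweep(pb, 2, colMeans(pb))
  f <- function(ang) {
    r <- euler_rotation(ang)
    sqrt(mean(rowSums((qb %*% t(r) - qa)^2)))
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    o <- stats::optim(runif(3, -pi, pi), f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
    if (o$value < best) best <- o$value
  }
  best
}
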