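# Shared phantom builders and independent brute-force oracles.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Asymmetric bumpy sphere: a generic closed surface with no rotational or
# mirror symmetry, for transform-recovery tests.
bumpy_mesh <- function(radius = 5, subdivisions = 3L) {
  ic <- icosphere(radius, subdivisions)
  v <- ic$vertices
  r <- 1 + 0.12 * sin(2 * v[, 1] + 1) + 0.09 * sin(3 * v[, 2] - v[, 3]) +
    0.07 * cos(v[, 1] * v[, 3])
  triangle_mesh(v * r, ic$faces)
}

# Axis-aligned unit cube as 12 consistently oriented triangles.
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # y-z faces handled via winding below
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6))
  triangle_mesh(v, f)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}

rotation_angle_deg <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(t(R2) %*% R1))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# Independent inside/outside oracle: pure-R ray-crossing parity along a
# fixed direction, vectorized over faces (Moller-Trumbore).
oracle_inside <- function(points, mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  d <- c(0.3141592, 0.6180339, 0.7210987)
  d <- d / sqrt(sum(d^2))
  pv <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
              d[3] * e2[, 1] - d[1] * e2[, 3],
              d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  apply(points, 1, function(p) {
    tv <- sweep(a, 2, p, "-") * -1
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    v <- (d[1] * qv[, 1] + d[2] * qv[, 2] + d[3] * qv[, 3]) / det
    t <- rowSums(e2 * qv) / det
    hit <- ok & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 & t > 1e-9
    sum(hit) %% 2 == 1
  })
}

# Brute-force inner/outer labelling: dense sampling of each center-vertex
# segment against the inside oracle.
oracle_classify <- function(mesh, n_samples = 60L) {
  ctr <- mesh_center(mesh)
  v <- mesh$vertices
  ts <- seq(0.01, 0.985, length.out = n_samples)
  vapply(seq_len(nrow(v)), function(i) {
    seg <- outer(1 - ts, ctr) + outer(ts, v[i, ])
    as.integer(any(oracle_inside(seg, mesh)))
  }, integer(1))
}

# Brute-force contour split: per point, count proper intersections of the
# (shrunk) center-point segment with every polygon edge not in the point's
# own neighbourhood. Independent plain-R reimplementation of the rule.
oracle_split <- function(pts, excl_radius = 2) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vapply(seq_len(n), function(i) {
    p <- pts[i, ]
    dirv <- p - ctr
    len <- sqrt(sum(dirv^2))
    if (len < 1e-9) return(0L)
    shrink <- min(0.75 * excl_radius / len, 0.45)
    q <- p - shrink * dirv
    s <- q - ctr
    hits <- 0L
    for (j in seq_len(n)) {
      j2 <- if (j == n) 1L else j + 1L
      aa <- pts[j, ]; bb <- pts[j2, ]
      if (sum((aa - p)^2) <= excl_radius^2 &&
          sum((bb - p)^2) <= excl_radius^2) next
      e <- bb - aa
      denom <- s[1] * e[2] - s[2] * e[1]
      if (abs(denom) < 1e-12) next
      t <- ((aa[1] - ctr[1]) * e[2] - (aa[2] - ctr[2]) * e[1]) / denom
      u <- ((aa[1] - ctr[1]) * s[2] - (aa[2] - ctr[2]) * s[1]) / denom
      if (t > 1e-9 && t < 1 - 1e-9 && u >= 0 && u < 1) hits <- hits + 1L
    }
    as.integer(hits > 0L)
  }, integer(1))
}

# Binary STL writer (for testing the binary reader against files produced
# outside the package's own ASCII writer).
write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  f <- mesh$faces
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- mesh$vertices[f[i, ], , drop = FALSE]
    writeBin(c(0, 0, 0, as.vector(t(tri))), con, size = 4L,
             endian = "little")
    writeBin(as.integer(0), con, size = 2L, endian = "little")
  }
}
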