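# shared fixtures: small meshes and point sets built in code

# points on a circle in 3D: center c0, radius r, unit normal n
circle_points <- function(n_pts, center, radius, normal, jitter_sd = 0,
                          axial_sd = 0) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
  B <- acetav:::plane_basis(acetav:::as_unit(normal))
  pts <- t(center + radius * (B[, 1] %o% cos(th) + B[, 2] %o% sin(th)))
  if (jitter_sd > 0) pts <- pts + matrix(rnorm(3 * n_pts, 0, jitter_sd), ncol = 3)
  if (axial_sd > 0) pts <- pts + rnorm(n_pts, 0, axial_sd) %o% acetav:::as_unit(normal)
  pts
}

# axis-aligned unit cube as 12 triangles (corner at origin)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  new_mesh(v, f)
}

# open flat plate in the x-y plane, (n+1)^2 grid vertices
plate_mesh <- function(n = 10, spacing = 1) {
  g <- expand.grid(x = 0:n, y = 0:n)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  f <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_len(n), function(j) {
      a <- (i - 1) * (n + 1) + j
      b <- i * (n + 1) + j
      rbind(c(a, b, a + 1), c(a + 1, b, b + 1))
    }))
  }))
  new_mesh(v, f)
}

# UV sphere of given radius
sphere_mesh <- function(radius = 25, n_u = 48, n_v = 24, center = c(0, 0, 0)) {
  s <- acetav:::ellipsoid_mesh(center, rep(radius, 3), n_u, n_v)
  new_mesh(s$vertices, s$faces)
}

# open cylinder (no caps), axis +z
cylinder_mesh <- function(radius = 20, height = 60, n_th = 60, n_z = 30) {
  th <- seq(0, 2 * pi, length.out = n_th + 1)[-(n_th + 1)]
  zs <- seq(0, height, length.out = n_z)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  idx <- function(i, j) (i - 1) * n_th + ((j - 1) %% n_th) + 1
  f <- do.call(rbind, lapply(seq_len(n_z - 1), function(i) {
    j <- seq_len(n_th)
    rbind(cbind(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
          cbind(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1)))
  }))
  new_mesh(v, f)
}

random_unit <- function() acetav:::as_unit(rnorm(3))

app_landmarks <- function() {
  new_landmarks(list(ASISL = c(120, 0, 0), ASISR = c(-120, 0, 0),
                     PT = c(0, 0, -90)))
}
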