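#' @title 3D geometric primitives
#' @name geometry
#' @description Plane fitting, robust circle fitting with outlier rejection,
#'   rigid rotations and angle computations used by every measurement stage.
#'   All lengths are millimetres; all angles cross the API boundary in degrees.
NULL

DEG <- 180 / pi

as_unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("zero-length vector where a direction is required")
  v / n
}

#' Construct a plane from a point and a normal
#'
#' @param point numeric length-3 point on the plane (mm).
#' @param normal numeric length-3 normal; normalised internally.
#' @return An object of class `av_plane` with fields `point` and unit `normal`.
#' @export
new_plane <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3, all(is.finite(point)))
  structure(list(point = as.numeric(point), normal = as_unit(as.numeric(normal))),
            class = "av_plane")
}

#' @export
print.av_plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.3f, %.3f, %.3f)  normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Total-least-squares plane through a point cloud
#'
#' Minimises the sum of squared orthogonal distances. The returned `point` is
#' the centroid; the normal's sign is unconstrained (callers orient it
#' anatomically).
#'
#' @param points numeric matrix, n x 3 (n >= 3), not all collinear.
#' @return `av_plane` with an `rms` attribute (root-mean-square orthogonal
#'   residual, mm).
#' @export
fit_plane <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x, nu = 0)
  # collinear: second singular value vanishes relative to the first
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-10)
    stop("degenerate input: points are collinear")
  normal <- sv$v[, 3]
  pl <- new_plane(ctr, normal)
  attr(pl, "rms") <- sqrt(mean((x %*% normal)^2))
  pl
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must be n x 3")
  if (!all(is.finite(points))) stop("non-finite coordinates")
  points
}

#' Angle between two vectors
#'
#' @param u,v non-zero numeric length-3 vectors.
#' @return Angle in degrees in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  u <- as_unit(as.numeric(u))
  v <- as_unit(as.numeric(v))
  acos(max(-1, min(1, sum(u * v)))) * DEG
}

#' Rotation matrix about an axis (right-hand rule)
#'
#' @param axis unit-length numeric length-3 axis.
#' @param angle_deg rotation angle, degrees.
#' @return 3 x 3 orthonormal matrix, determinant +1.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  k <- as_unit(as.numeric(axis))
  th <- angle_deg / DEG
  kx <- matrix(c(0, k[3], -k[2],
                 -k[3], 0, k[1],
                 k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Rigidly rotate a geometric object
#'
#' Right-hand-rule rotation about an axis through a pivot point. Methods exist
#' for bare points/vectors (numeric vector or n x 3 matrix), [new_mesh()]
#' meshes and landmark sets.
#'
#' @param x object to rotate.
#' @param axis unit rotation axis.
#' @param angle_deg angle in degrees.
#' @param pivot point the axis passes through (default origin).
#' @return Object of the same type, rotated.
#' @export
rotate_rigid <- function(x, axis, angle_deg, pivot = c(0, 0, 0)) {
  UseMethod("rotate_rigid")
}

rotate_points <- function(p, axis, angle_deg, pivot) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(p, 2, pivot) %*% t(R), 2, pivot, `+`)
}

#' @export
rotate_rigid.default <- function(x, axis, angle_deg, pivot = c(0, 0, 0)) {
  if (is.null(dim(x))) {
    drop(rotate_points(matrix(as.numeric(x), 1, 3), axis, angle_deg, pivot))
  } else {
    rotate_points(as_point_matrix(x), axis, angle_deg, pivot)
  }
}

#' @export
rotate_rigid.av_mesh <- function(x, axis, angle_deg, pivot = c(0, 0, 0)) {
  x$vertices <- rotate_points(x$vertices, axis, angle_deg, pivot)
  x
}

#' @export
rotate_rigid.av_landmarks <- function(x, axis, angle_deg, pivot = c(0, 0, 0)) {
  x$points <- rotate_points(x$points, axis, angle_deg, pivot)
  x
}

#' @export
rotate_rigid.av_plane <- function(x, axis, angle_deg, pivot = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  new_plane(drop(rotate_points(matrix(x$point, 1, 3), axis, angle_deg, pivot)),
            drop(R %*% x$normal))
}

# orthonormal in-plane basis (u, v) completing a unit normal n
plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- as_unit(a - sum(a * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, v)
}

# Kasa algebraic circle fit on 2D coordinates; returns c(cx, cy, r)
kasa_fit <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- qr.solve(A, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) stop("circle fit failed: non-positive squared radius")
  c(sol[1], sol[2], sqrt(r2))
}

# residuals: exact 3D point-to-circle distances
circle3d_residuals <- function(points, center, normal, radius) {
  d <- sweep(points, 2, center)
  h <- d %*% normal
  rad <- d - h %*% t(normal)
  rho <- sqrt(rowSums(rad^2))
  sqrt((rho - radius)^2 + h^2)
}

# geometric circle objective for given axis direction n (unit) on points:
# optimal plane offset and radius are closed-form, in-plane center free.
# params = c(theta, phi, a, b): axis in spherical coords, in-plane center
# offsets from the centroid along the axis-completing basis.
circle3d_objective <- function(par, points, ctr0) {
  n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  B <- plane_basis(n)
  center0 <- ctr0 + B %*% par[3:4]
  d <- sweep(points, 2, drop(center0))
  h <- d %*% n
  # optimal shift of the center along n zeroes the mean axial residual
  hbar <- mean(h)
  h <- h - hbar
  rad <- d - (h + hbar) %*% t(n)
  rho <- sqrt(rowSums(rad^2))
  r <- mean(rho)
  sum((rho - r)^2 + h^2)
}

circle3d_from_par <- function(par, points, ctr0) {
  n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  B <- plane_basis(n)
  center0 <- drop(ctr0 + B %*% par[3:4])
  d <- sweep(points, 2, center0)
  h <- d %*% n
  center <- center0 + mean(h) * n
  d <- sweep(points, 2, center)
  rad <- d - (d %*% n) %*% t(n)
  r <- mean(sqrt(rowSums(rad^2)))
  list(center = center, normal = n, radius = r)
}

#' Robust 3D circle fit with iterative outlier rejection
#'
#' Fits a circle in 3D space to a point cloud (typically the delineated
#' acetabular rim): a total-least-squares plane is fitted, points are
#' projected and an algebraic (Kasa) circle fit initialises a geometric
#' refinement that minimises the sum of squared true 3D point-to-circle
#' distances. Points whose residual exceeds `outlier_threshold` scaled median
#' absolute deviations are discarded and the fit repeated until stable.
#' This makes the fit robust to gross outliers such as osteophyte-distorted
#' rim vertices.
#'
#' @param points n x 3 matrix of rim points (mm), n >= 6, not all collinear.
#' @param outlier_threshold residual threshold in scaled MAD units
#'   (default 3.5).
#' @param max_iterations maximum outlier-rejection rounds (default 5).
#' @return An `av_circle3d`: `center` (mm), `radius` (mm), unit `normal`, and
#'   `fit` report (`n_points`, `n_outliers_removed`, `rms_residual`,
#'   `inliers` index vector).
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 60)
#' pts <- cbind(25 * cos(th), 25 * sin(th), 0)
#' fit_circle3d(pts)
fit_circle3d <- function(points, outlier_threshold = 3.5, max_iterations = 5) {
  points <- as_point_matrix(points)
  if (nrow(points) < 6) stop("circle fit needs at least 6 points")
  stopifnot(outlier_threshold > 0, max_iterations >= 1)

  idx <- seq_len(nrow(points))
  n_removed <- 0L
  fit <- NULL
  for (iter in seq_len(max_iterations)) {
    pts <- points[idx, , drop = FALSE]
    if (nrow(pts) < 6) stop("circle fit failed: too many points flagged as outliers")
    fit <- circle3d_once(pts)
    res <- circle3d_residuals(pts, fit$center, fit$normal, fit$radius)
    s <- stats::mad(res, center = 0)
    bad <- res > outlier_threshold * max(s, 1e-9)
    if (!any(bad)) break
    if (sum(!bad) < 6) stop("circle fit failed: too many points flagged as outliers")
    n_removed <- n_removed + sum(bad)
    idx <- idx[!bad]
  }
  res <- circle3d_residuals(points[idx, , drop = FALSE], fit$center, fit$normal, fit$radius)
  structure(list(center = fit$center, radius = fit$radius, normal = fit$normal,
                 fit = list(n_points = nrow(points),
                            n_outliers_removed = n_removed,
                            rms_residual = sqrt(mean(res^2)),
                            inliers = idx)),
            class = "av_circle3d")
}

# one plane + Kasa + geometric refinement pass (no outlier handling).
# The refinement runs in a canonical frame derived equivariantly from the
# data (SVD axes, signs fixed by coordinate skewness), so a rigid transform
# of the input transforms the fitted circle exactly rather than to optimiser
# tolerance.
circle3d_once <- function(pts) {
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-10)
    stop("degenerate input: points are collinear")
  E <- sv$v
  # canonical signs: positive skewness along the first and third axes,
  # right-handed completion for the second
  s1 <- sum((X %*% E[, 1])^3)
  if (s1 < 0) E[, 1] <- -E[, 1]
  s3 <- sum((X %*% E[, 3])^3)
  if (s3 < 0) E[, 3] <- -E[, 3]
  E[, 2] <- c(E[2, 3] * E[3, 1] - E[3, 3] * E[2, 1],
              E[3, 3] * E[1, 1] - E[1, 3] * E[3, 1],
              E[1, 3] * E[2, 1] - E[2, 3] * E[1, 1])
  local <- X %*% E # plane normal is local +z (third axis)

  # tip the frame so the axis is away from the spherical-coordinate pole
  Rf <- rotation_matrix(c(1, 0, 0), 45)
  ptsL <- local %*% t(Rf)
  n0 <- drop(Rf %*% c(0, 0, 1))
  B <- plane_basis(n0)
  xy <- ptsL %*% B
  k <- kasa_fit(xy)
  f <- circle3d_once_frame(ptsL, n0, c(0, 0, 0), drop(B %*% k[1:2]), k[3])

  back <- function(p) drop(E %*% drop(t(Rf) %*% p))
  list(center = ctr + back(f$center),
       normal = back(f$normal),
       radius = f$radius)
}

circle3d_once_frame <- function(pts, n0, ctr0, center_init, r_init) {
  theta0 <- acos(max(-1, min(1, n0[3])))
  phi0 <- atan2(n0[2], n0[1])
  B0 <- plane_basis(n0)
  ab0 <- drop(t(B0) %*% (center_init - ctr0))
  par0 <- c(theta0, phi0, ab0)
  f0 <- circle3d_objective(par0, pts, ctr0)
  opt <- stats::optim(par0, circle3d_objective, points = pts, ctr0 = ctr0,
                      method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  # polish: restarting BFGS rebuilds the Hessian approximation and squeezes
  # out the last digits, keeping the minimum frame-independent
  opt2 <- stats::optim(opt$par, circle3d_objective, points = pts, ctr0 = ctr0,
                       method = "BFGS",
                       control = list(reltol = 1e-15, maxit = 200))
  best <- if (opt2$value <= opt$value) opt2 else opt
  par <- if (best$value <= f0) best$par else par0
  circle3d_from_par(par, pts, ctr0)
}

#' @export
print.av_circle3d <- function(x, ...) {
  cat(sprintf(paste0("<circle3d> center (%.3f, %.3f, %.3f) mm  radius %.3f mm\n",
                     "  normal (%.4f, %.4f, %.4f)  rms %.4g mm  (%d pts, %d outliers removed)\n"),
              x$center[1], x$center[2], x$center[3], x$radius,
              x$normal[1], x$normal[2], x$normal[3],
              x$fit$rms_residual, x$fit$n_points, x$fit$n_outliers_removed))
  invisible(x)
}

# signed distance of points from a plane along its normal
plane_distance <- function(plane, points) {
  points <- as_point_matrix(points)
  drop(sweep(points, 2, plane$point) %*% plane$normal)
}
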