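test_that("plane fit recovers exact planes and matches the covariance oracle", {
  # exact: four points with z = 5
  pl <- fit_plane(rbind(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5), c(3, -2, 5)))
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_lt(attr(pl, "rms"), 1e-12)

  # three exact points define their plane with zero residual
  p3 <- rbind(c(0, 0, 0), c(1, 0, 1), c(0, 1, 2))
  pl3 <- fit_plane(p3)
  expect_lt(max(abs(acetav:::plane_distance(pl3, p3))), 1e-12)

  # noisy samples: normal within 0.5 degrees of the eigen-decomposition
  # oracle (smallest eigenvector of the point covariance)
  set.seed(101)
  n0 <- acetav:::as_unit(c(0.3, -0.8, 0.52))
  B <- acetav:::plane_basis(n0)
  uv <- matrix(runif(400, -40, 40), ncol = 2)
  pts <- uv %*% t(B) + matrix(rnorm(600, 0, 0.2), ncol = 3)
  pl <- fit_plane(pts)
  ev <- eigen(stats::cov(pts))$vectors[, 3]
  ang <- angle_between(pl$normal, ev)
  expect_lt(min(ang, 180 - ang), 0.5)
  # and both agree with the generating normal
  ang0 <- angle_between(pl$normal, n0)
  expect_lt(min(ang0, 180 - ang0), 0.5)

  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  expect_error(fit_plane(cbind(1:10, 1:10, 1:10)), "collinear")
})

test_that("circle fit is exact on clean data and robust to axial outliers", {
  pts <- circle_points(100, c(0, 0, 0), 25, c(0, 0, 1))
  circ <- fit_circle3d(pts)
  expect_equal(circ$radius, 25, tolerance = 1e-9)
  expect_lt(max(abs(circ$center)), 1e-9)
  expect_equal(abs(circ$normal[3]), 1, tolerance = 1e-9)
  expect_equal(circ$fit$n_outliers_removed, 0)

  # 10% of points displaced 5 mm along the axis are flagged, and the fit
  # stays within 0.1 mm of the fit on the clean subset
  set.seed(7)
  bad <- sample(100, 10)
  pts_o <- pts
  pts_o[bad, 3] <- pts_o[bad, 3] + 5
  co <- fit_circle3d(pts_o)
  cc <- fit_circle3d(pts[-bad, ])
  expect_equal(co$fit$n_outliers_removed, 10)
  expect_false(any(bad %in% co$fit$inliers))
  expect_lt(abs(co$radius - cc$radius), 0.1)
  expect_lt(sqrt(sum((co$center - cc$center)^2)), 0.1)

  expect_error(fit_circle3d(pts[1:5, ]), "at least 6")
  expect_error(fit_circle3d(cbind(1:10, 2 * (1:10), 3 * (1:10))), "collinear")
})

test_that("circle fit is equivariant under rigid transforms", {
  set.seed(23)
  for (rep in 1:5) {
    th <- runif(120, 0, 2 * pi)
    pts <- cbind(25 * cos(th) + 4, 25 * sin(th) - 9, rnorm(120, 0, 0.3))
    ax <- random_unit(); ang <- runif(1, 0, 360); tr <- rnorm(3, 0, 40)
    R <- rotation_matrix(ax, ang)
    c1 <- fit_circle3d(pts)
    c2 <- fit_circle3d(sweep(pts %*% t(R), 2, tr, `+`))
    expect_lt(abs(c1$radius - c2$radius), 1e-9)
    expect_lt(sqrt(sum((drop(R %*% c1$center) + tr - c2$center)^2)), 1e-6)
    nerr <- angle_between(drop(R %*% c1$normal), c2$normal)
    expect_lt(min(nerr, 180 - nerr), 1e-4)
  }
})

test_that("geometric refinement does not increase the sum of squared residuals", {
  set.seed(31)
  for (rep in 1:5) {
    pts <- circle_points(80, rnorm(3, 0, 10), 20 + runif(1, 0, 10),
                         random_unit(), jitter_sd = 0.5)
    pl <- acetav:::fit_plane(pts)
    B <- acetav:::plane_basis(pl$normal)
    xy <- sweep(pts, 2, pl$point) %*% B
    k <- acetav:::kasa_fit(xy)
    init_center <- drop(pl$point + B %*% k[1:2])
    ssr_init <- sum(acetav:::circle3d_residuals(pts, init_center, pl$normal, k[3])^2)
    circ <- fit_circle3d(pts, outlier_threshold = 1e6) # keep all points
    ssr_fit <- sum(acetav:::circle3d_residuals(pts, circ$center, circ$normal,
                                               circ$radius)^2)
    expect_lte(ssr_fit, ssr_init + 1e-9)
  }
})

test_that("angle_between handles the canonical cases and is symmetric", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 0, 0)), 180)
  set.seed(5)
  for (rep in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    a <- angle_between(u, v)
    expect_equal(angle_between(v, u), a, tolerance = 1e-12)
    expect_equal(angle_between(3.7 * u, 0.02 * v), a, tolerance = 1e-9)
  }
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("rotation follows the right-hand rule and inverts cleanly", {
  expect_equal(rotate_rigid(c(0, -1, 0), c(1, 0, 0), 90),
               c(0, 0, -1), tolerance = 1e-12)
  v <- c(3, -2, 7)
  expect_equal(rotate_rigid(v, c(0, 0, 1), 0), v, tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:10) {
    ax <- random_unit(); ang <- runif(1, -180, 180); piv <- rnorm(3, 0, 20)
    w <- rotate_rigid(rotate_rigid(v, ax, ang, piv), ax, -ang, piv)
    expect_equal(w, v, tolerance = 1e-12)
  }
  R <- rotation_matrix(c(0, 0, 1), 90)
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
})
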