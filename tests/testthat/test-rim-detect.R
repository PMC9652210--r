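test_that("discrete mean curvature matches analytic values on model surfaces", {
  # sphere of radius 25: H = 1/25
  sp <- sphere_mesh(25)
  cv <- as.numeric(vertex_curvature(sp))
  expect_equal(median(cv), 1 / 25, tolerance = 0.1)

  # open cylinder radius 20: mean curvature 1/(2*20); boundary rings excluded
  cy <- cylinder_mesh(20, 60)
  cvc <- as.numeric(vertex_curvature(cy))
  interior <- cy$vertices[, 3] > 5 & cy$vertices[, 3] < 55
  expect_equal(median(cvc[interior]), 1 / 40, tolerance = 0.1)

  # flat plate: interior curvature ~ 0
  pm <- plate_mesh(10)
  cvp <- as.numeric(vertex_curvature(pm))
  interior <- pm$vertices[, 1] > 0 & pm$vertices[, 1] < 10 &
    pm$vertices[, 2] > 0 & pm$vertices[, 2] < 10
  expect_lt(max(cvp[interior]), 1e-6)
})

test_that("curvature field validates input and flags degenerate faces", {
  m <- cube_mesh()
  expect_length(as.numeric(vertex_curvature(m)), 8)
  # mesh with one zero-area triangle
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4)) # second face is collinear
  expect_warning(vertex_curvature(new_mesh(v, f)), "zero-area")
})

test_that("rim selection on the clean phantom hugs the true rim circle", {
  ph <- make_phantom(phantom_spec())
  curv <- vertex_curvature(ph$mesh)
  rim <- select_rim(ph$mesh, curv, seed = landmark(ph$landmarks, "RIM_SEED"))
  expect_gte(rim$n_vertices, 6)
  pts <- ph$mesh$vertices[rim$vertices, ]
  tc <- ph$truth$rim_circle
  d <- sweep(pts, 2, tc$center)
  h <- drop(d %*% tc$normal)
  rho <- sqrt(rowSums((d - h %o% tc$normal)^2))
  dist_to_circle <- sqrt((rho - tc$radius)^2 + h^2)
  expect_lt(max(dist_to_circle), 1.5)
})

test_that("rim detection fails cleanly on a featureless surface", {
  pm <- plate_mesh(15)
  curv <- vertex_curvature(pm)
  expect_error(select_rim(pm, curv), "rim detection failed")
})

test_that("circle fitted from a noisy phantom rim recovers the radius within 2%", {
  for (s in c(3, 14)) {
    ph <- make_phantom(phantom_spec(vertex_noise_sd_mm = 0.3, rng_seed = s))
    curv <- vertex_curvature(ph$mesh)
    rim <- select_rim(ph$mesh, curv, seed = landmark(ph$landmarks, "RIM_SEED"))
    circ <- fit_circle3d(ph$mesh$vertices[rim$vertices, ])
    expect_lt(abs(circ$radius - 25) / 25, 0.02)
  }
})

test_that("raising the percentile never enlarges the selection", {
  ph <- make_phantom(phantom_spec(vertex_noise_sd_mm = 0.2, rng_seed = 2))
  curv <- vertex_curvature(ph$mesh)
  seed <- landmark(ph$landmarks, "RIM_SEED")
  sizes <- vapply(c(85, 90, 95), function(p) {
    select_rim(ph$mesh, curv, seed = seed, percentile = p)$n_vertices
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("rim selection is invariant under rigid transforms of the mesh", {
  # a touch of surface noise breaks the exact per-ring curvature ties of the
  # ideal phantom, which make set equality at the threshold ill-posed
  ph <- make_phantom(phantom_spec(vertex_noise_sd_mm = 0.1, rng_seed = 6))
  curv <- vertex_curvature(ph$mesh)
  seed <- landmark(ph$landmarks, "RIM_SEED")
  rim0 <- select_rim(ph$mesh, curv, seed = seed)
  ax <- c(1, 2, -1) / sqrt(6)
  m2 <- rotate_rigid(ph$mesh, ax, 63, c(10, 5, -40))
  seed2 <- rotate_rigid(seed, ax, 63, c(10, 5, -40))
  rim2 <- select_rim(m2, vertex_curvature(m2), seed = seed2)
  expect_identical(rim0$vertices, rim2$vertices)
})

test_that("manual rim lists are validated and usable", {
  ph <- make_phantom(phantom_spec())
  curv <- vertex_curvature(ph$mesh)
  auto <- select_rim(ph$mesh, curv, seed = landmark(ph$landmarks, "RIM_SEED"))
  man <- manual_rim(ph$mesh, auto$vertices)
  expect_equal(man$vertices, auto$vertices)
  expect_identical(man$source, "manual")
  expect_error(manual_rim(ph$mesh, 1:3), "at least 6")
  expect_error(manual_rim(ph$mesh, c(1:6, 10^7)), "out of range")
})
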