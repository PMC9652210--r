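#' @title Parametric hemipelvis phantom with exact ground truth
#' @name phantom
#' @description A deliberately non-anatomical synthetic pelvis: a smooth body
#'   ellipsoid (standing in for the bony pelvis bulk) plus a cup assembly --
#'   a hemispherical acetabular bowl meeting a flat annular flange at a sharp
#'   rim crest -- whose rim circle, anterior pelvic plane and anteversion
#'   angle are all known in closed form. Every stage of the measurement chain
#'   (curvature rim detection, circle fitting, plane construction, axial
#'   slicing, 2D reading, tilt simulation) can therefore be validated against
#'   exact ground truth without clinical data.
NULL

#' Phantom specification
#'
#' @param true_av_deg ground-truth anteversion angle (degrees; in (-40, 50)).
#' @param true_inclination_deg cup inclination: caudal tip of the cup axis in
#'   the coronal plane (degrees, default 45 -- a typical acetabular
#'   inclination, and the driver of the 2D overestimation).
#' @param rim_radius_mm rim circle radius (default 25).
#' @param cup_depth_fraction fraction of the full hemisphere kept (default
#'   0.85: the bony socket is shy of a complete hemisphere).
#' @param side `"left"` or `"right"`.
#' @param vertex_noise_sd_mm isotropic Gaussian vertex noise SD (default 0).
#' @param mesh_resolution scaling factor for tessellation density (default 1).
#' @param rim_fillet_mm radius of a chamfer blending flange into bowl at the
#'   rim; 0 = perfectly sharp crest (default 0).
#' @param asis_halfspan_mm half distance between the ASIS landmarks
#'   (default 120).
#' @param pt_drop_mm caudal offset of the pubic tubercle landmark
#'   (default 95).
#' @param cup_center_mm cup centre (= femoral head centre) for a left-side
#'   phantom; mirrored in X for the right (default `c(85, -5, -30)`).
#' @param rng_seed seed for the vertex noise (default 0).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(true_av_deg = 16.1,
                         true_inclination_deg = 45,
                         rim_radius_mm = 25,
                         cup_depth_fraction = 0.85,
                         side = c("left", "right"),
                         vertex_noise_sd_mm = 0,
                         mesh_resolution = 1,
                         rim_fillet_mm = 0,
                         asis_halfspan_mm = 120,
                         pt_drop_mm = 95,
                         cup_center_mm = c(85, -5, -30),
                         rng_seed = 0) {
  side <- match.arg(side)
  stopifnot(rim_radius_mm > 0, vertex_noise_sd_mm >= 0,
            cup_depth_fraction > 0, cup_depth_fraction <= 1,
            mesh_resolution > 0)
  if (true_av_deg <= -40 || true_av_deg >= 50)
    stop("true_av_deg outside the supported (-40, 50) range")
  structure(list(true_av_deg = true_av_deg,
                 true_inclination_deg = true_inclination_deg,
                 rim_radius_mm = rim_radius_mm,
                 cup_depth_fraction = cup_depth_fraction,
                 side = side,
                 vertex_noise_sd_mm = vertex_noise_sd_mm,
                 mesh_resolution = mesh_resolution,
                 rim_fillet_mm = rim_fillet_mm,
                 asis_halfspan_mm = asis_halfspan_mm,
                 pt_drop_mm = pt_drop_mm,
                 cup_center_mm = cup_center_mm,
                 rng_seed = rng_seed),
            class = "phantom_spec")
}

# outward rim-plane normal for given AV, inclination and side, in LPS:
# lateral component cos(AV)cos(I) toward the cup side, anterior component
# sin(AV) (i.e. y = -sin(AV)), caudal component -cos(AV)sin(I). Unit by
# construction, and angle(normal, anterior) = 90 - AV exactly.
phantom_rim_normal <- function(av_deg, incl_deg, side) {
  av <- av_deg / DEG
  ii <- incl_deg / DEG
  sx <- if (side == "left") 1 else -1
  c(sx * cos(av) * cos(ii), -sin(av), -cos(av) * sin(ii))
}

# run RNG code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# UV tessellation of an ellipsoid; returns vertices/faces
ellipsoid_mesh <- function(center, semi, n_u, n_v) {
  th <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  ph <- seq(0, pi, length.out = n_v + 2)[-c(1, n_v + 2)]
  ring <- function(phv) cbind(semi[1] * sin(phv) * cos(th),
                              semi[2] * sin(phv) * sin(th),
                              semi[3] * cos(phv))
  verts <- do.call(rbind, lapply(ph, ring))
  npole <- c(0, 0, semi[3]); spole <- c(0, 0, -semi[3])
  verts <- rbind(verts, npole, spole)
  ni <- nrow(verts) - 1L; si <- nrow(verts)
  idx <- function(i, j) (i - 1L) * n_u + ((j - 1L) %% n_u) + 1L
  faces <- list()
  for (i in seq_len(n_v - 1)) {
    j <- seq_len(n_u)
    faces[[i]] <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                        cbind(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1)))
  }
  j <- seq_len(n_u)
  cap_n <- cbind(rep(ni, n_u), idx(1, j), idx(1, j + 1))
  cap_s <- cbind(rep(si, n_u), idx(n_v, j + 1), idx(n_v, j))
  faces <- do.call(rbind, c(faces, list(cap_n, cap_s)))
  list(vertices = sweep(verts, 2, center, `+`), faces = faces)
}

# cup assembly in a local frame (rim plane z = 0, axis +z, bowl below):
# spherical bowl meeting an annular flange R..R_out at the rim crest ring.
# Ring spacing is graded -- finest (base_step) at the crest, growing away
# from it -- so the crest band dominates the high-curvature percentile the
# way a segmented acetabular ridge dominates a real curvature plot.
cup_mesh_local <- function(R, R_out, depth_fraction, n_theta,
                           base_step = 0.72, growth = 1.6, fillet_mm = 0) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  rings <- list()
  # flange radii from the outer edge in toward the rim (outer boundary open)
  fr <- R
  k <- 0L
  repeat {
    step <- if (k < 2L) base_step else base_step * growth^(k - 1L)
    if (fr[length(fr)] >= R_out) break
    fr <- c(fr, min(fr[length(fr)] + step, R_out))
    k <- k + 1L
  }
  for (r in rev(fr[-1]))
    rings[[length(rings) + 1]] <- cbind(r * cos(th), r * sin(th), 0)
  if (fillet_mm > 0) {
    # chamfer rings blending flange into bowl (blunts the crest)
    for (a in c(pi / 6, pi / 3)) {
      r <- R - fillet_mm * (1 - cos(a))
      z <- -fillet_mm * sin(a)
      rings[[length(rings) + 1]] <- cbind(r * cos(th), r * sin(th), z)
    }
  } else {
    # rim crest ring: exactly the ground-truth circle
    rings[[length(rings) + 1]] <- cbind(R * cos(th), R * sin(th), 0)
  }
  # bowl rings: colatitude from the rim (pi/2) toward the pole, graded
  phi_end <- pi / 2 * (1 - depth_fraction)
  phv <- pi / 2
  k <- 0L
  repeat {
    dphi <- if (k < 2L) base_step / R else base_step * growth^(k - 1L) / R
    phv <- phv - dphi
    if (phv <= phi_end + 1e-9) break
    rings[[length(rings) + 1]] <- cbind(R * sin(phv) * cos(th),
                                        R * sin(phv) * sin(th),
                                        -R * cos(phv))
    k <- k + 1L
  }
  verts <- do.call(rbind, rings)
  nr <- length(rings)
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- list()
  for (i in seq_len(nr - 1)) {
    j <- seq_len(n_theta)
    faces[[i]] <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                        cbind(idx(i, j + 1), idx(i + 1, j), idx(i + 1, j + 1)))
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Generate the phantom mesh, landmarks and ground truth
#'
#' Builds the two-component phantom surface in the LPS scanner frame with a
#' neutral supine pose: the APP is the plane y = 0 (anterior normal
#' `(0, -1, 0)`), the cup axis is set from `true_av_deg` and
#' `true_inclination_deg` so that the anteversion recomputed from the true
#' planes equals `true_av_deg` exactly. Vertex noise, if requested, is
#' isotropic Gaussian, seeded, and applied to mesh vertices only (landmarks
#' are treated as expert-labelled and exact). Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `mesh` ([new_mesh()]), `landmarks` (`av_landmarks` with
#'   ASISL/ASISR/PT, FHC_L/FHC_R, SN_L/SN_R, IT_L/IT_R, AR_ANT/AR_POST,
#'   RIM_SEED), and `truth` (`phantom_truth`: `rim_circle`, `app`,
#'   `true_av_deg`, `cup_center`, `side`, `body_center`, `body_semi`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$rim_radius_mm
  side_sign <- if (spec$side == "left") 1 else -1
  cc <- spec$cup_center_mm * c(side_sign, 1, 1)
  n <- phantom_rim_normal(spec$true_av_deg, spec$true_inclination_deg, spec$side)

  body_center <- c(0, 20, -30)
  body_semi <- c(110, 45, 70)
  if (R >= min(body_semi)) stop("cup larger than the body extent")

  res <- spec$mesh_resolution
  body <- ellipsoid_mesh(body_center, body_semi,
                         n_u = max(24, round(60 * res)),
                         n_v = max(12, round(41 * res)))
  cup <- cup_mesh_local(R, R_out = 40, depth_fraction = spec$cup_depth_fraction,
                        n_theta = max(36, round(120 * res)),
                        base_step = 0.72 / res,
                        fillet_mm = spec$rim_fillet_mm)
  # orient local +z to the rim normal and translate to the cup centre
  B <- plane_basis(n)
  M <- cbind(B[, 1], B[, 2], n)
  cup_v <- cup$vertices %*% t(M)
  cup_v <- sweep(cup_v, 2, cc, `+`)

  verts <- rbind(body$vertices, cup_v)
  faces <- rbind(body$faces, cup$faces + nrow(body$vertices))

  if (spec$vertex_noise_sd_mm > 0) {
    # spatially correlated displacement field: white Gaussian noise smoothed
    # over the mesh graph and rescaled to the requested SD. Emulates CT
    # segmentation error (voxel-scale correlated surface deviation) rather
    # than per-vertex white roughness, which no segmented surface shows.
    noise <- with_seed(spec$rng_seed,
                       matrix(stats::rnorm(length(verts)), ncol = 3))
    for (k in 1:3) noise[, k] <- smooth_field(noise[, k], faces, 3)
    noise <- sweep(noise, 2, apply(noise, 2, stats::sd), `/`) *
      spec$vertex_noise_sd_mm
    verts <- verts + noise
  }
  mesh <- new_mesh(verts, faces)

  # landmarks (exact, in the APP plane y = 0 for ASIS/PT)
  ez <- function(x, z) {
    # y on the posterior half of the body ellipsoid at given x, z
    t <- 1 - (x / body_semi[1])^2 - ((z - body_center[3]) / body_semi[3])^2
    body_center[2] + body_semi[2] * sqrt(max(t, 0))
  }
  zs <- cc[3] # slice level: both head centres share this z
  truth_circle <- structure(list(center = cc, radius = R, normal = n,
                                 fit = list(n_points = NA_integer_,
                                            n_outliers_removed = 0L,
                                            rms_residual = 0,
                                            inliers = integer(0))),
                            class = "av_circle3d")
  arp <- phantom_rim_slice_points_impl(cc, R, n, zs)
  lm <- new_landmarks(list(
    ASISL = c(spec$asis_halfspan_mm, 0, 0),
    ASISR = c(-spec$asis_halfspan_mm, 0, 0),
    PT = c(0, 0, -spec$pt_drop_mm),
    FHC_L = c(abs(cc[1]), cc[2], cc[3]),
    FHC_R = c(-abs(cc[1]), cc[2], cc[3]),
    SN_L = c(60, ez(60, zs), zs),
    SN_R = c(-60, ez(-60, zs), zs),
    IT_L = c(55, ez(55, -75), -75),
    IT_R = c(-55, ez(-55, -75), -75),
    AR_ANT = arp$anterior,
    AR_POST = arp$posterior,
    RIM_SEED = cc + R * drop(plane_basis(n)[, 1])
  ))

  truth <- structure(list(
    rim_circle = truth_circle,
    app = new_plane(c(0, 0, 0), c(0, -1, 0)),
    true_av_deg = spec$true_av_deg,
    true_inclination_deg = spec$true_inclination_deg,
    cup_center = cc,
    side = spec$side,
    body_center = body_center,
    body_semi = body_semi
  ), class = "phantom_truth")

  list(mesh = mesh, landmarks = lm, truth = truth, spec = spec)
}

# analytic intersection of the rim circle with the axial plane z = z0
phantom_rim_slice_points_impl <- function(center, R, n, z0) {
  B <- plane_basis(n)
  u <- B[, 1]; v <- B[, 2]
  # solve center_z + R (cos t u_z + sin t v_z) = z0
  A <- R * u[3]; Bz <- R * v[3]; Cz <- z0 - center[3]
  rr <- sqrt(A^2 + Bz^2)
  if (rr < abs(Cz)) stop("axial plane does not intersect the rim circle")
  ph <- atan2(Bz, A)
  base <- acos(max(-1, min(1, Cz / rr)))
  t1 <- ph + base; t2 <- ph - base
  p1 <- center + R * (cos(t1) * u + sin(t1) * v)
  p2 <- center + R * (cos(t2) * u + sin(t2) * v)
  if (p1[2] < p2[2]) list(anterior = p1, posterior = p2)
  else list(anterior = p2, posterior = p1)
}

#' Analytic rim-circle crossings of an axial plane
#'
#' Closed-form anterior and posterior rim points of the phantom's true rim
#' circle in the axial plane `z = z0`; the oracle for the 2D slice reading.
#'
#' @param truth a `phantom_truth` from [make_phantom()].
#' @param z0 axial plane height (mm); defaults to the cup centre level.
#' @return list with 3D points `anterior` and `posterior`.
#' @export
phantom_rim_slice_points <- function(truth, z0 = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(z0)) z0 <- truth$cup_center[3]
  phantom_rim_slice_points_impl(truth$cup_center, truth$rim_circle$radius,
                                truth$rim_circle$normal, z0)
}

#' Anteversion recomputed from the ground-truth planes
#'
#' Self-consistency check: AV = 90 - angle(outward rim normal, anterior APP
#' normal), evaluated on the exact truth objects.
#'
#' @param truth a `phantom_truth`.
#' @return AV in degrees (equals `true_av_deg` to numerical precision).
#' @export
phantom_true_av <- function(truth) {
  90 - angle_between(truth$rim_circle$normal, truth$app$normal)
}

#' Simulate a measurement cohort
#'
#' Draws a cohort with the statistical structure of a two-sided hip study:
#' per subject a sex (female with probability `p_female`) and pose angles
#' lambda / rho, per hemipelvis a true 3D anteversion from the sex-specific
#' normal distribution and a 2D reading offset by a linear pose-dependent
#' bias: `av2d = av3d - (b0 + b_lambda*lambda + b_rho*rho +
#' b_interaction*lambda*rho + e)`, `e ~ N(0, noise_sd)`. Default parameters
#' reproduce the printed cohort moments of the source study population (male
#' 14.0 (5.4), female 18.4 (5.6); bias slope 0.474 on lambda, -0.318 on rho).
#'
#' @param n_subjects number of subjects (two hemipelvises each; default 129).
#' @param sex_effect list `male_mean, male_sd, female_mean, female_sd,
#'   p_female`.
#' @param tilt_model list `lambda_mean, lambda_sd, rho_mean, rho_sd` (pose is
#'   drawn per subject: both sides share one scan).
#' @param bias_model list `b0, b_lambda, b_rho, b_interaction, noise_sd`.
#' @param bmi_probs probabilities of BMI classes `<18.5`, `18.5-25`, `>25`.
#' @param rng_seed RNG seed (default 0).
#' @return A tibble (class `av_cohort`): `subject_id, side, sex, bmi_class,
#'   av3d_deg, av2d_deg, lambda_deg, rho_deg`.
#' @export
make_cohort <- function(n_subjects = 129,
                        sex_effect = list(male_mean = 14.0, male_sd = 5.4,
                                          female_mean = 18.4, female_sd = 5.6,
                                          p_female = 61 / 129),
                        tilt_model = list(lambda_mean = 65, lambda_sd = 7.3,
                                          rho_mean = 0, rho_sd = 2),
                        bias_model = list(b0 = -36.643, b_lambda = 0.474,
                                          b_rho = -0.318, b_interaction = 0,
                                          noise_sd = 3.5),
                        bmi_probs = c(6, 54, 69) / 129,
                        rng_seed = 0) {
  stopifnot(n_subjects >= 4,
            sex_effect$male_sd > 0, sex_effect$female_sd > 0,
            tilt_model$lambda_sd > 0, tilt_model$rho_sd > 0,
            bias_model$noise_sd >= 0)
  with_seed(rng_seed, {
    sex <- ifelse(stats::runif(n_subjects) < sex_effect$p_female, "female", "male")
    lam <- stats::rnorm(n_subjects, tilt_model$lambda_mean, tilt_model$lambda_sd)
    rho <- stats::rnorm(n_subjects, tilt_model$rho_mean, tilt_model$rho_sd)
    bmi <- sample(c("<18.5", "18.5-25", ">25"), n_subjects, replace = TRUE,
                  prob = bmi_probs)
    df <- tidyr::expand_grid(subject_id = seq_len(n_subjects),
                             side = c("left", "right"))
    df$sex <- sex[df$subject_id]
    df$bmi_class <- bmi[df$subject_id]
    df$lambda_deg <- lam[df$subject_id]
    df$rho_deg <- rho[df$subject_id]
    mu <- ifelse(df$sex == "male", sex_effect$male_mean, sex_effect$female_mean)
    sd <- ifelse(df$sex == "male", sex_effect$male_sd, sex_effect$female_sd)
    df$av3d_deg <- stats::rnorm(nrow(df), mu, sd)
    bias <- bias_model$b0 +
      bias_model$b_lambda * df$lambda_deg +
      bias_model$b_rho * df$rho_deg +
      bias_model$b_interaction * df$lambda_deg * df$rho_deg +
      stats::rnorm(nrow(df), 0, bias_model$noise_sd)
    df$av2d_deg <- df$av3d_deg - bias
    out <- tibble::as_tibble(df)
    class(out) <- c("av_cohort", class(out))
    out
  })
}
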