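#' @title Pelvic pose angles and the virtual tilt experiment
#' @name pose_tilt
#' @description Quantifies how the pelvis lies relative to the scanner table
#'   axes (DICOM frame: X transverse, Y vertical for a supine subject,
#'   Z longitudinal) with two angles -- lambda, the anterior-posterior pelvic
#'   tilt, and rho, the lateral pelvic tilt -- and provides the virtual tilt
#'   sweep that demonstrates the pose dependence of the 2D measurement while
#'   the 3D measurement stays constant.
NULL

#' Anterior-posterior pelvic tilt (lambda)
#'
#' Signed angle, in the sagittal (Y-Z) plane, between the neutral anterior
#' direction (-Y) and the projection of the anterior APP normal. The sign is
#' defined constructively: applying a right-hand-rule rotation of +theta
#' about +X to a neutral pelvis yields lambda = +theta.
#'
#' @param app the anterior pelvic plane ([anterior_pelvic_plane()]), with
#'   anteriorly oriented normal.
#' @return lambda in degrees, in (-180, 180\].
#' @export
compute_lambda <- function(app) {
  n <- app$normal
  if (sqrt(n[2]^2 + n[3]^2) < 1e-9)
    stop("degenerate pose: APP normal parallel to the transverse axis X")
  # rotation about +X maps (0,-1,0) to (0, -cos t, -sin t)
  atan2(-n[3], -n[2]) * DEG
}

#' Lateral pelvic tilt (rho)
#'
#' Signed angle between the ASISR -> ASISL vector and the transverse table
#' axis +X, measured in the coronal (X-Z) plane; positive when the left ASIS
#' lies cranial to the right.
#'
#' @param landmarks an `av_landmarks` with ASISL and ASISR.
#' @return rho in degrees.
#' @export
compute_rho <- function(landmarks) {
  v <- landmark(landmarks, "ASISL") - landmark(landmarks, "ASISR")
  if (sqrt(sum(v^2)) < 1e-9) stop("ASISL and ASISR coincide")
  if (sqrt(v[1]^2 + v[3]^2) < 1e-9 * sqrt(sum(v^2)))
    stop("degenerate pose: ASIS vector parallel to the vertical axis Y")
  atan2(v[3], v[1]) * DEG
}

#' Virtual pelvic-tilt sweep
#'
#' Rigidly rotates the pelvis (mesh + 3D landmarks) in steps about the
#' scanner's transverse axis (`axis = "AP"`: anterior-posterior tilt, about
#' +X) or vertical axis (`axis = "lateral"`: lateral tilt, about +Y), with
#' the pivot at the midpoint of the femoral head centres. At every step the
#' 2D measurement is re-taken exactly as a radiologist would re-read the
#' tilted scan -- the axial cut is re-selected at the rotated head-centre
#' level and the slice landmarks re-snapped -- while the 3D measurement is
#' recomputed from the rotated surface. The 3D angle stays constant; the 2D
#' angle does not.
#'
#' @param mesh an [new_mesh()] mesh.
#' @param landmarks an `av_landmarks` with APP landmarks, FHC_L/FHC_R and the
#'   slice seeds used by [compute_av2d()].
#' @param axis `"AP"` or `"lateral"`.
#' @param range_deg sweep limits in degrees (default `c(-10, 10)`).
#' @param step_deg step (default 1).
#' @param variant 2D reference variant (default `"stem"`).
#' @param rim optional fixed `av_rim` reused at every step (exact 3D pose
#'   invariance); when `NULL` the rim is re-detected per pose.
#' @param ... passed to [compute_av3d()].
#' @return A tibble (class `av_tilt_sweep`), one row per step:
#'   `applied_tilt_deg`, `axis`, `av2d_deg`, `av3d_deg`, `lambda_deg`,
#'   `rho_deg`, `ok` (FALSE where slice extraction failed at extreme tilt).
#' @export
tilt_sweep <- function(mesh, landmarks, axis = c("AP", "lateral"),
                       range_deg = c(-10, 10), step_deg = 1,
                       variant = "stem", rim = NULL, ...) {
  axis <- match.arg(axis)
  # lateral tilt about the (vertical) -Y axis so that positive applied tilt
  # raises the left ASIS cranially, i.e. rho equals the applied angle
  rot_axis <- if (axis == "AP") c(1, 0, 0) else c(0, -1, 0)
  pivot <- (landmark(landmarks, "FHC_L") + landmark(landmarks, "FHC_R")) / 2
  angles <- if (diff(range_deg) == 0) range_deg[1] else
    seq(range_deg[1], range_deg[2], by = step_deg)

  if (is.null(rim)) {
    curv <- vertex_curvature(mesh)
    seed <- if (has_landmark(landmarks, "RIM_SEED")) landmark(landmarks, "RIM_SEED") else NULL
    rim <- select_rim(mesh, curv, seed = seed)
  }

  rows <- purrr::map(angles, function(th) {
    m <- rotate_rigid(mesh, rot_axis, th, pivot)
    lm <- rotate_rigid(landmarks, rot_axis, th, pivot)
    app <- anterior_pelvic_plane(lm, mesh = m)
    lam <- compute_lambda(app)
    rho <- compute_rho(lm)
    r3 <- compute_av3d(m, lm, rim = rim, ...)
    r2 <- tryCatch(compute_av2d(m, lm, variant = variant),
                   error = function(e) NULL)
    tibble::tibble(
      applied_tilt_deg = th,
      axis = axis,
      av2d_deg = if (is.null(r2)) NA_real_ else r2$angle_deg,
      av3d_deg = r3$angle_deg,
      lambda_deg = lam,
      rho_deg = rho,
      ok = !is.null(r2)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("av_tilt_sweep", class(out))
  out
}

#' Plot a tilt sweep
#'
#' The twin of the tilt-simulation figure: 2D and 3D AV angles against the
#' applied tilt. The 3D curve is flat; the 2D curve is not.
#'
#' @param object an `av_tilt_sweep` tibble from [tilt_sweep()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.av_tilt_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("av2d_deg", "av3d_deg"),
                            names_to = "method", values_to = "av_deg")
  df$method <- ifelse(df$method == "av2d_deg", "2D (axial slice)", "3D (rim plane)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$applied_tilt_deg, y = .data$av_deg,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = sprintf("applied %s tilt (degrees)", object$axis[1]),
                  y = "measured AV angle (degrees)", colour = NULL) +
    ggplot2::theme_minimal()
}
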