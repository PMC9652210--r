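#' @title True 3D anteversion measurement
#' @name av3d
#' @description The 3D anteversion angle is measured between two anatomical
#'   planes: the acetabular plane (carrying the fitted rim circle, normal
#'   oriented out of the cup) and the anterior pelvic plane (APP, through
#'   ASISL, ASISR and PT, normal oriented anteriorly). With alpha the angle
#'   between the two normals, AV = 90 - alpha. Because both planes are
#'   intrinsic to the bone, the measurement is independent of how the pelvis
#'   lies in the scanner.
NULL

#' Anterior pelvic plane from the three standard landmarks
#'
#' Plane through the left and right anterior superior iliac spines (ASISL,
#' ASISR) and the most forward protruding point of the pubic tubercles (PT).
#' The normal is oriented anteriorly: in the LPS frame that is the sign with
#' negative +Y component; when a mesh is supplied, the normal points away
#' from the side of the plane holding the mesh centroid (valid in any pose).
#'
#' @param landmarks an `av_landmarks` containing ASISL, ASISR, PT.
#' @param mesh optional mesh used to orient the normal for arbitrary poses.
#' @return An `av_plane` with anteriorly oriented unit normal.
#' @export
anterior_pelvic_plane <- function(landmarks, mesh = NULL) {
  a <- landmark(landmarks, "ASISL")
  b <- landmark(landmarks, "ASISR")
  p <- landmark(landmarks, "PT")
  if (sqrt(sum((a - b)^2)) < 1e-9) stop("ASISL and ASISR coincide")
  n <- pracma_cross(b - a, p - a)
  if (sqrt(sum(n^2)) < 1e-9 * sqrt(sum((b - a)^2)) )
    stop("APP landmarks are collinear")
  pl <- new_plane((a + b + p) / 3, n)
  if (!is.null(mesh)) {
    ctr <- colMeans(mesh$vertices)
    if (sum((ctr - pl$point) * pl$normal) > 0) pl$normal <- -pl$normal
  } else if (pl$normal[2] > 0) {
    pl$normal <- -pl$normal
  }
  pl
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Acetabular plane from the fitted rim circle
#'
#' The plane carrying the rim circle, with the normal oriented away from the
#' cup interior (outward: lateral-anterior for an anteverted socket).
#'
#' @param rim_circle an `av_circle3d` from [fit_circle3d()].
#' @param cup_interior_point a 3D point inside the cup (e.g. the centroid of
#'   the cup surface vertices); must not lie on the rim plane.
#' @return An `av_plane`.
#' @export
acetabular_plane <- function(rim_circle, cup_interior_point) {
  stopifnot(inherits(rim_circle, "av_circle3d"))
  pl <- new_plane(rim_circle$center, rim_circle$normal)
  s <- sum((as.numeric(cup_interior_point) - pl$point) * pl$normal)
  if (abs(s) < 1e-9) stop("cup interior point lies on the rim plane; cannot orient")
  if (s > 0) pl$normal <- -pl$normal
  pl
}

# centroid of mesh vertices within one rim radius of the rim centre on the
# concave (cup) side of the rim plane
cup_interior_point <- function(mesh, rim_circle, rim_vertices = NULL) {
  v <- mesh$vertices
  d <- sweep(v, 2, rim_circle$center)
  within <- rowSums(d^2) <= (1.0 * rim_circle$radius)^2
  h <- drop(d %*% rim_circle$normal)
  # the concave (cup) side of the rim plane holds the bowl vertices; pick the
  # side with more vertices inside one rim radius
  neg <- within & (h < -1e-6)
  pos <- within & (h > 1e-6)
  sel <- if (sum(neg) >= sum(pos)) neg else pos
  if (sum(sel) < 1) stop("cannot locate cup interior: no vertices under the rim plane")
  colMeans(v[sel, , drop = FALSE])
}

#' Compute the 3D anteversion angle
#'
#' Runs the full 3D pipeline on a mesh: delineate the rim (automatically via
#' curvature unless a rim is supplied), fit the robust rim circle, orient the
#' acetabular plane out of the cup, build the APP from the landmarks, and
#' return AV = 90 - alpha. AV > 0 indicates anteversion (the cup opening tips
#' anteriorly), AV < 0 retroversion.
#'
#' @param mesh an [new_mesh()] pelvis mesh.
#' @param landmarks an `av_landmarks` with ASISL, ASISR, PT (a rim seed
#'   landmark `RIM_SEED` is used for detection when present).
#' @param rim optional `av_rim` (from [select_rim()] or [manual_rim()]);
#'   detected automatically when `NULL`.
#' @param side `"left"`, `"right"` or `NULL` to infer from the rim centre
#'   (positive X = left in the LPS frame).
#' @param ... passed to [select_rim()] (e.g. `percentile`).
#' @return A one-row tibble (class `av_result`): `method`, `side`,
#'   `angle_deg`, `alpha_deg`, `rim_n`, `rim_source`, `fit_rms`,
#'   `n_outliers_removed`; the planes and circle are attached as attributes
#'   `acetabular_plane`, `reference_plane`, `rim_circle`.
#' @export
compute_av3d <- function(mesh, landmarks, rim = NULL, side = NULL, ...) {
  stopifnot(inherits(mesh, "av_mesh"), inherits(landmarks, "av_landmarks"))
  if (is.null(rim)) {
    curv <- vertex_curvature(mesh)
    seed <- if (has_landmark(landmarks, "RIM_SEED")) landmark(landmarks, "RIM_SEED") else NULL
    rim <- select_rim(mesh, curv, seed = seed, ...)
  }
  circ <- fit_circle3d(mesh$vertices[rim$vertices, , drop = FALSE])
  interior <- cup_interior_point(mesh, circ)
  acet <- acetabular_plane(circ, interior)
  app <- anterior_pelvic_plane(landmarks, mesh = mesh)
  alpha <- angle_between(acet$normal, app$normal)
  av <- 90 - alpha
  if (is.null(side)) side <- if (circ$center[1] >= 0) "left" else "right"
  res <- tibble::tibble(
    method = "av3d",
    side = side,
    angle_deg = av,
    alpha_deg = alpha,
    rim_n = rim$n_vertices,
    rim_source = rim$source,
    fit_rms = circ$fit$rms_residual,
    n_outliers_removed = circ$fit$n_outliers_removed
  )
  class(res) <- c("av_result", class(res))
  attr(res, "acetabular_plane") <- acet
  attr(res, "reference_plane") <- app
  attr(res, "rim_circle") <- circ
  res
}
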