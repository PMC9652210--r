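#' @title 2D axial-slice anteversion measurement
#' @name av2d
#' @description Emulates the classical 2D measurement of acetabular
#'   anteversion on a single axial CT cut, realised here as a cross-section
#'   of the surface mesh at the level of the femoral head centres. Two
#'   reference variants are provided: the posterior-margin line (transischial
#'   line or the posterior pelvic margins at the sciatic notch) and the line
#'   through the femoral head centres. The AV angle is read between the
#'   acetabular-margin line and the perpendicular to the reference line.
#'   This measurement, unlike the 3D one, depends on pelvic tilt.
NULL

#' Axial slice level from the femoral head centres
#'
#' The standard cut is the axial plane closest to both femoral head centres:
#' the mean of their Z coordinates.
#'
#' @param landmarks an `av_landmarks` with FHC_L and FHC_R.
#' @return slice z-level in mm.
#' @export
select_slice_level <- function(landmarks) {
  (landmark(landmarks, "FHC_L")[3] + landmark(landmarks, "FHC_R")[3]) / 2
}

#' Intersect a mesh with an axial plane
#'
#' Computes the plane-mesh intersection segments at `z = z_level` and chains
#' them into ordered contour polylines (closed where the surface is closed,
#' open across surface boundaries).
#'
#' @param mesh an [new_mesh()] mesh.
#' @param z_level axial plane height (mm).
#' @return An `av_slice`: `z_level` and `contours`, a list of k x 2 matrices
#'   of (x, y) points, each with a `closed` attribute.
#' @export
axial_slice <- function(mesh, z_level) {
  stopifnot(inherits(mesh, "av_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  # nudge off exact vertex hits for a generic-position cut
  if (any(abs(v[, 3] - z_level) < 1e-9)) z_level <- z_level + 1e-7

  zs <- matrix(v[f, 3], ncol = 3) - z_level
  below <- zs < 0
  nb <- rowSums(below)
  cross <- nb == 1L | nb == 2L
  if (!any(cross)) stop("empty slice: plane z = ", z_level, " does not intersect the mesh")
  fc <- f[cross, , drop = FALSE]

  seg_a <- matrix(NA_real_, nrow(fc), 2)
  seg_b <- matrix(NA_real_, nrow(fc), 2)
  edge_pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  zc <- matrix(v[fc, 3], ncol = 3) - z_level
  for (i in seq_len(nrow(fc))) {
    pts <- NULL
    for (ep in edge_pairs) {
      za <- zc[i, ep[1]]; zb <- zc[i, ep[2]]
      if ((za < 0) != (zb < 0)) {
        t <- za / (za - zb)
        pa <- v[fc[i, ep[1]], ]; pb <- v[fc[i, ep[2]], ]
        pts <- rbind(pts, pa[1:2] + t * (pb[1:2] - pa[1:2]))
      }
    }
    seg_a[i, ] <- pts[1, ]
    seg_b[i, ] <- pts[2, ]
  }

  contours <- chain_segments(seg_a, seg_b)
  structure(list(z_level = z_level, contours = contours), class = "av_slice")
}

# chain unordered 2D segments into polylines by matching endpoints
chain_segments <- function(a, b, tol = 1e-6) {
  n <- nrow(a)
  key <- function(p) paste(round(p[, 1] / tol), round(p[, 2] / tol))
  ka <- key(a); kb <- key(b)
  pts <- rbind(a, b)
  keys <- c(ka, kb)
  uk <- unique(keys)
  node <- match(keys, uk)        # 2n entries: node id of each segment end
  ends <- cbind(node[1:n], node[(n + 1):(2 * n)])
  # adjacency: for each node, incident segments
  used <- logical(n)
  inc <- split(rep(seq_len(n), 2), c(ends[, 1], ends[, 2]))
  coords <- matrix(NA_real_, length(uk), 2)
  coords[node, ] <- pts

  contours <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    # walk forward from segment s0
    path <- integer(0)
    used[s0] <- TRUE
    path_nodes <- c(ends[s0, 1], ends[s0, 2])
    repeat {
      tail_node <- path_nodes[length(path_nodes)]
      nxt <- inc[[as.character(tail_node)]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      sn <- nxt[1]
      used[sn] <- TRUE
      other <- if (ends[sn, 1] == tail_node) ends[sn, 2] else ends[sn, 1]
      path_nodes <- c(path_nodes, other)
      if (other == path_nodes[1]) break
    }
    # walk backward from the head if open
    if (path_nodes[length(path_nodes)] != path_nodes[1]) {
      repeat {
        head_node <- path_nodes[1]
        nxt <- inc[[as.character(head_node)]]
        nxt <- nxt[!used[nxt]]
        if (length(nxt) == 0) break
        sn <- nxt[1]
        used[sn] <- TRUE
        other <- if (ends[sn, 1] == head_node) ends[sn, 2] else ends[sn, 1]
        path_nodes <- c(other, path_nodes)
      }
    }
    closed <- path_nodes[length(path_nodes)] == path_nodes[1] && length(path_nodes) > 3
    if (closed) path_nodes <- path_nodes[-length(path_nodes)]
    poly <- coords[path_nodes, , drop = FALSE]
    attr(poly, "closed") <- closed
    contours[[length(contours) + 1]] <- poly
  }
  contours
}

#' @export
print.av_slice <- function(x, ...) {
  cat(sprintf("<axial slice> z = %.3f mm, %d contour(s) with %s points\n",
              x$z_level, length(x$contours),
              paste(vapply(x$contours, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

# signed 2D AV angle between the acetabular-margin line and the perpendicular
# of the reference line. Positive = anteversion: walking from the posterior
# to the anterior rim point moves medially (toward the midline x = 0).
av2d_angle <- function(ar_ant, ar_post, ref_a, ref_b) {
  ar_ant <- as.numeric(ar_ant)[1:2]; ar_post <- as.numeric(ar_post)[1:2]
  ref_a <- as.numeric(ref_a)[1:2]; ref_b <- as.numeric(ref_b)[1:2]
  m <- ar_ant - ar_post
  r <- ref_b - ref_a
  if (sqrt(sum(m^2)) < 1e-9) stop("acetabular margin points coincide")
  if (sqrt(sum(r^2)) < 1e-9) stop("reference points coincide")
  p <- c(-r[2], r[1]) / sqrt(sum(r^2))        # perpendicular of reference line
  if (p[2] > 0) p <- -p                        # orient anteriorly (-Y)
  m <- m / sqrt(sum(m^2))
  if (sum(m * p) < 0) m <- -m                  # lines, not vectors
  theta <- acos(max(-1, min(1, sum(m * p)))) * DEG
  medial <- c(-sign(mean(c(ar_ant[1], ar_post[1]))), 0)
  sgn <- if (sum((ar_ant - ar_post) * medial) >= 0) 1 else -1
  sgn * theta
}

#' 2D anteversion, posterior-margin reference (Stem-type)
#'
#' Angle between the acetabular margin line (posterior to anterior rim point)
#' and the perpendicular to the posterior reference line (through the ischial
#' tuberosities or the posterior pelvic margins at the sciatic notch).
#' Positive values indicate anteversion.
#'
#' @param ar_ant,ar_post anterior/posterior acetabular rim points in the
#'   slice (2D, mm).
#' @param ref_a,ref_b the two posterior reference points (2D, mm).
#' @return signed AV angle in degrees.
#' @export
measure_av2d_stem <- function(ar_ant, ar_post, ref_a, ref_b) {
  av2d_angle(ar_ant, ar_post, ref_a, ref_b)
}

#' 2D anteversion, femoral-head-centre reference (Tallroth-type)
#'
#' As [measure_av2d_stem()], but the reference line joins the two femoral
#' head centres.
#'
#' @param ar_ant,ar_post anterior/posterior acetabular rim points (2D, mm).
#' @param fhc_l,fhc_r femoral head centres projected into the slice (2D, mm).
#' @return signed AV angle in degrees.
#' @export
measure_av2d_tallroth <- function(ar_ant, ar_post, fhc_l, fhc_r) {
  av2d_angle(ar_ant, ar_post, fhc_l, fhc_r)
}

#' Snap projected landmark seeds onto slice contours
#'
#' Automates what a radiologist does when reading the cut: each 3D seed
#' landmark is projected into the slice plane and snapped to the closest
#' point on any contour segment within a capture radius.
#'
#' @param slice an `av_slice`.
#' @param seeds an `av_landmarks` (3D seeds; only x, y are used).
#' @param names which landmarks to extract (default: all in `seeds`).
#' @param capture_radius_mm maximum seed-to-contour distance (default 10).
#' @return named matrix of 2D points (one row per landmark).
#' @export
extract_slice_landmarks <- function(slice, seeds, names = NULL,
                                    capture_radius_mm = 10) {
  stopifnot(inherits(slice, "av_slice"), inherits(seeds, "av_landmarks"))
  if (is.null(names)) names <- rownames(seeds$points)
  out <- matrix(NA_real_, length(names), 2, dimnames = list(names, c("x", "y")))
  for (nm in names) {
    s <- landmark(seeds, nm)[1:2]
    best <- c(Inf, NA, NA)
    for (poly in slice$contours) {
      k <- nrow(poly)
      if (k < 2) next
      idx2 <- if (isTRUE(attr(poly, "closed"))) c(2:k, 1) else 2:k
      idx1 <- if (isTRUE(attr(poly, "closed"))) 1:k else 1:(k - 1)
      a <- poly[idx1, , drop = FALSE]
      b <- poly[idx2, , drop = FALSE]
      ab <- b - a
      len2 <- rowSums(ab^2)
      t <- ((s[1] - a[, 1]) * ab[, 1] + (s[2] - a[, 2]) * ab[, 2]) / pmax(len2, 1e-300)
      t <- pmin(pmax(t, 0), 1)
      px <- a[, 1] + t * ab[, 1]
      py <- a[, 2] + t * ab[, 2]
      d2 <- (px - s[1])^2 + (py - s[2])^2
      j <- which.min(d2)
      if (d2[j] < best[1]) best <- c(d2[j], px[j], py[j])
    }
    if (!is.finite(best[1]) || sqrt(best[1]) > capture_radius_mm)
      stop("slice landmark extraction failed: no contour point within ",
           capture_radius_mm, " mm of ", nm)
    out[nm, ] <- best[2:3]
  }
  out
}

#' Compute the 2D anteversion angle on a mesh cross-section
#'
#' Full 2D pipeline: pick the slice level from the femoral head centres
#' (unless `z_level` is given), cut the mesh, snap the acetabular rim seeds
#' (AR_ANT, AR_POST) and -- for the posterior-margin variant -- the
#' posterior reference seeds (SN_L/SN_R, falling back to IT_L/IT_R) onto the
#' contours, and measure the angle.
#'
#' @param mesh an [new_mesh()] mesh.
#' @param landmarks an `av_landmarks` with AR_ANT, AR_POST, FHC_L, FHC_R and,
#'   for `variant = "stem"`, SN_L/SN_R or IT_L/IT_R.
#' @param variant `"stem"` (posterior margin reference, default) or
#'   `"tallroth"` (femoral-head-centre reference).
#' @param z_level optional explicit slice height (mm).
#' @param side `"left"`, `"right"` or `NULL` to infer from the rim seeds.
#' @param capture_radius_mm seed snapping radius (default 10).
#' @return One-row tibble (class `av_result`): `method`, `side`, `angle_deg`,
#'   `z_level`; the slice and extracted 2D points attached as attributes.
#' @export
compute_av2d <- function(mesh, landmarks, variant = c("stem", "tallroth"),
                         z_level = NULL, side = NULL, capture_radius_mm = 10) {
  variant <- match.arg(variant)
  if (is.null(z_level)) z_level <- select_slice_level(landmarks)
  slice <- axial_slice(mesh, z_level)
  ar <- extract_slice_landmarks(slice, landmarks, c("AR_ANT", "AR_POST"),
                                capture_radius_mm)
  if (variant == "stem") {
    refs <- if (has_landmark(landmarks, "SN_L") && has_landmark(landmarks, "SN_R"))
      c("SN_L", "SN_R") else c("IT_L", "IT_R")
    rf <- extract_slice_landmarks(slice, landmarks, refs, capture_radius_mm)
    ang <- measure_av2d_stem(ar["AR_ANT", ], ar["AR_POST", ], rf[1, ], rf[2, ])
  } else {
    fl <- landmark(landmarks, "FHC_L")[1:2]
    fr <- landmark(landmarks, "FHC_R")[1:2]
    ang <- measure_av2d_tallroth(ar["AR_ANT", ], ar["AR_POST", ], fl, fr)
  }
  if (is.null(side)) side <- if (mean(ar[, 1]) >= 0) "left" else "right"
  res <- tibble::tibble(
    method = paste0("av2d_", variant),
    side = side,
    angle_deg = ang,
    z_level = z_level
  )
  class(res) <- c("av_result", class(res))
  attr(res, "slice") <- slice
  attr(res, "points2d") <- ar
  res
}
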