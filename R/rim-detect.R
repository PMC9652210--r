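#' @title Acetabular rim delineation
#' @name rim_detect
#' @description The acetabular rim is the sharp bony crest around the hip
#'   socket. On a triangle mesh it shows up as a band of high surface
#'   curvature, which is thresholded and traced as a connected loop; the loop
#'   feeds the robust circle fit that defines the acetabular plane.
NULL

#' Discrete mean-curvature magnitude per vertex
#'
#' Cotangent-Laplacian mean curvature with mixed-Voronoi vertex areas
#' (Voronoi area for non-obtuse triangles, T/2 at the obtuse corner and T/4
#' elsewhere otherwise). Boundary vertices (on an edge used by a single face)
#' are assigned 0. Zero-area triangles are skipped with a warning.
#'
#' @param mesh an [new_mesh()] triangle mesh.
#' @return numeric vector of curvature magnitudes (1/mm), one per vertex,
#'   class `av_curvature`.
#' @export
vertex_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "av_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)

  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e23 <- p3 - p2; e31 <- p1 - p3; e12 <- p2 - p1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr(e12, -e31)^2)) # 2 * triangle area
  degen <- area2 <= .Machine$double.eps
  if (all(degen)) stop("fully degenerate mesh: all triangles have zero area")
  if (any(degen)) {
    warning(sum(degen), " zero-area triangle(s) skipped in curvature computation")
    f <- f[!degen, , drop = FALSE]
    p1 <- p1[!degen, , drop = FALSE]; p2 <- p2[!degen, , drop = FALSE]
    p3 <- p3[!degen, , drop = FALSE]
    e23 <- e23[!degen, , drop = FALSE]; e31 <- e31[!degen, , drop = FALSE]
    e12 <- e12[!degen, , drop = FALSE]
    area2 <- area2[!degen]
  }

  # cotangents of the angle at each corner
  cot1 <- rowSums((-e31) * e12) / area2   # angle at vertex 1, between e12 and -e31
  cot2 <- rowSums((-e12) * e23) / area2
  cot3 <- rowSums((-e23) * e31) / area2

  # Laplacian sum: for edge (i, j) opposite corner k, weight cot_k applies to
  # (p_i - p_j) at i and (p_j - p_i) at j.
  ii <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  dx <- rbind(-e12, e12, -e23, e23, -e31, e31) # p_i - p_j per (i, j) pair
  w <- c(cot3, cot3, cot1, cot1, cot2, cot2)
  lap <- matrix(0, nv, 3)
  acc <- function(vals) {
    out <- numeric(nv)
    s <- rowsum(vals, ii)
    out[as.integer(rownames(s))] <- s
    out
  }
  lap[, 1] <- acc(w * dx[, 1])
  lap[, 2] <- acc(w * dx[, 2])
  lap[, 3] <- acc(w * dx[, 3])

  # mixed Voronoi areas (Meyer et al. construction)
  obtuse1 <- cot1 < 0; obtuse2 <- cot2 < 0; obtuse3 <- cot3 < 0
  anyobt <- obtuse1 | obtuse2 | obtuse3
  tA <- area2 / 2
  l23 <- rowSums(e23^2); l31 <- rowSums(e31^2); l12 <- rowSums(e12^2)
  a1 <- ifelse(anyobt, ifelse(obtuse1, tA / 2, tA / 4), (l12 * cot3 + l31 * cot2) / 8)
  a2 <- ifelse(anyobt, ifelse(obtuse2, tA / 2, tA / 4), (l12 * cot3 + l23 * cot1) / 8)
  a3 <- ifelse(anyobt, ifelse(obtuse3, tA / 2, tA / 4), (l23 * cot1 + l31 * cot2) / 8)
  amix <- numeric(nv)
  s <- rowsum(c(a1, a2, a3), c(f[, 1], f[, 2], f[, 3]))
  amix[as.integer(rownames(s))] <- s

  H <- sqrt(rowSums(lap^2)) / (4 * pmax(amix, .Machine$double.eps))

  # boundary vertices -> 0
  ek <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
              pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])))
  once <- names(which(table(ek) == 1))
  if (length(once)) {
    bidx <- unique(as.integer(unlist(strsplit(once, " "))))
    H[bidx] <- 0
  }
  H[amix == 0] <- 0
  structure(H, class = "av_curvature")
}

# undirected edge list of the mesh graph
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# k rounds of one-ring averaging of a per-vertex scalar field
smooth_field <- function(values, faces, iterations) {
  if (iterations <= 0) return(values)
  e <- mesh_edges(faces)
  nv <- length(values)
  for (i in seq_len(iterations)) {
    s <- numeric(nv)
    cnt <- numeric(nv)
    se <- rowsum(c(values[e[, 2]], values[e[, 1]]), c(e[, 1], e[, 2]))
    ce <- rowsum(rep(1, 2 * nrow(e)), c(e[, 1], e[, 2]))
    s[as.integer(rownames(se))] <- se
    cnt[as.integer(rownames(ce))] <- ce
    values <- (values + s) / (1 + cnt)
  }
  values
}

#' Select the high-curvature acetabular rim loop
#'
#' Thresholds the (optionally smoothed) curvature field at a percentile,
#' forms connected components on the mesh graph, picks the component nearest
#' the seed point (or the largest without a seed), and verifies that the
#' selected vertices actually encircle the cup: their angular span around a
#' preliminary fitted circle axis must exceed `min_span_deg`.
#'
#' @param mesh an [new_mesh()] mesh.
#' @param curvature per-vertex curvature from [vertex_curvature()].
#' @param seed optional 3D point near the rim (e.g. a labelled rim landmark);
#'   without it the largest component is taken.
#' @param percentile curvature percentile for the threshold (default 90).
#' @param smooth_iterations one-ring smoothing rounds applied to the field
#'   before thresholding (default 2; suppresses vertex-noise speckle).
#' @param min_span_deg required angular coverage of the rim loop (default 300).
#' @return An `av_rim`: `vertices` (indices), `source = "automatic"`,
#'   `n_vertices`.
#' @export
select_rim <- function(mesh, curvature, seed = NULL, percentile = 90,
                       smooth_iterations = 2, min_span_deg = 300) {
  stopifnot(inherits(mesh, "av_mesh"))
  curv <- as.numeric(curvature)
  if (length(curv) != nrow(mesh$vertices))
    stop("curvature field not aligned with mesh vertices")
  curv <- smooth_field(curv, mesh$faces, smooth_iterations)
  thr <- stats::quantile(curv, percentile / 100, names = FALSE)
  keep <- which(curv > thr)
  if (length(keep) < 6) stop("rim detection failed: no high-curvature region")

  e <- mesh_edges(mesh$faces)
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(e), keep), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(keep) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes >= 6)
  if (length(big) == 0) stop("rim detection failed: no connected high-curvature loop")

  if (is.null(seed)) {
    ci <- big[which.max(sizes[big])]
  } else {
    seed <- as.numeric(seed)
    d2 <- vapply(big, function(k) {
      idx <- keep[comp$membership == k]
      min(colSums((t(mesh$vertices[idx, , drop = FALSE]) - seed)^2))
    }, numeric(1))
    ci <- big[which.min(d2)]
  }
  sel <- keep[comp$membership == ci]

  # encirclement check around the preliminary circle axis
  circ <- fit_circle3d(mesh$vertices[sel, , drop = FALSE])
  B <- plane_basis(circ$normal)
  d <- sweep(mesh$vertices[sel, , drop = FALSE], 2, circ$center) %*% B
  ang <- sort(atan2(d[, 2], d[, 1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  span <- 360 - max(gaps) * DEG
  if (span < min_span_deg)
    stop(sprintf("rim detection failed: selected band spans only %.0f degrees", span))

  structure(list(vertices = sort(sel), source = "automatic",
                 n_vertices = length(sel)),
            class = "av_rim")
}

#' Use a manually delineated rim
#'
#' Mirrors a manually reviewed rim labelling: accepts an explicit vertex-index
#' list (e.g. from a JSON override file written as an array of 0- or 1-based
#' indices; pass `zero_based = TRUE` for the former).
#'
#' @param mesh an [new_mesh()] mesh.
#' @param vertices integer vertex indices (>= 6 unique, in range).
#' @param zero_based whether indices are 0-based (default `FALSE`).
#' @return An `av_rim` with `source = "manual"`.
#' @export
manual_rim <- function(mesh, vertices, zero_based = FALSE) {
  idx <- as.integer(vertices) + if (zero_based) 1L else 0L
  idx <- sort(unique(idx))
  if (length(idx) < 6) stop("manual rim needs at least 6 unique vertices")
  if (min(idx) < 1 || max(idx) > nrow(mesh$vertices)) stop("rim index out of range")
  structure(list(vertices = idx, source = "manual", n_vertices = length(idx)),
            class = "av_rim")
}

#' @export
print.av_rim <- function(x, ...) {
  cat(sprintf("<rim> %d vertices (%s)\n", x$n_vertices, x$source))
  invisible(x)
}
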