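#' @title Mesh and landmark input/output
#' @name mesh_io
#' @description Triangle surface meshes are read from STL (binary or ASCII;
#'   ASCII PLY accepted as an extension) in millimetre units, in the DICOM
#'   patient (LPS) frame for a supine subject: +X to patient left, +Y
#'   posterior, +Z cranial; anterior is -Y. STL carries no unit metadata, so
#'   millimetres are a documented contract. Landmarks are JSON files mapping
#'   anatomical names to `[x, y, z]` coordinates.
NULL

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param attributes optional named list of per-vertex scalar attributes.
#' @return An object of class `av_mesh`.
#' @export
new_mesh <- function(vertices, faces, attributes = list()) {
  vertices <- as_point_matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) == 0 || nrow(faces) == 0) stop("empty mesh")
  if (ncol(faces) != 3) stop("faces must be m x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face index out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]))
    stop("face references a repeated vertex")
  structure(list(vertices = vertices, faces = faces, attributes = attributes),
            class = "av_mesh")
}

#' @export
print.av_mesh <- function(x, ...) {
  cat(sprintf("<mesh> %d vertices, %d faces (mm, LPS frame)\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Weld duplicate vertices
#'
#' Merges vertices closer than `tolerance` (snap-to-grid) and drops faces
#' degenerated by the merge. Welding is idempotent.
#'
#' @param vertices n x 3 matrix; @param faces m x 3 index matrix.
#' @param tolerance merge tolerance in mm (default 1e-6).
#' @return list with welded `vertices` and re-indexed `faces`.
#' @export
weld_vertices <- function(vertices, faces, tolerance = 1e-6) {
  key <- paste(round(vertices[, 1] / tolerance),
               round(vertices[, 2] / tolerance),
               round(vertices[, 3] / tolerance))
  first <- !duplicated(key)
  map <- match(key, key[first])
  verts <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  list(vertices = verts, faces = faces[ok, , drop = FALSE])
}

#' Read a triangle mesh from STL or ASCII PLY
#'
#' Binary and ASCII STL are auto-detected; duplicate vertices are welded
#' (tolerance 1e-6 mm).
#'
#' @param path path to an `.stl` or ASCII `.ply` file.
#' @return An [new_mesh()] object.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    tri <- read_ply_ascii(path)
  } else {
    tri <- read_stl(path)
  }
  if (nrow(tri$faces) == 0) stop("mesh file contains no triangles: ", path)
  w <- weld_vertices(tri$vertices, tri$faces)
  new_mesh(w$vertices, w$faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(n)
  if (length(n) == 1 && !is.na(n) && file.size(path) == expected && n > 0) {
    raw <- readBin(con, "raw", 50 * n)
    m <- matrix(raw, nrow = 50)
    tri <- vapply(seq_len(n), function(i) {
      readBin(m[1:48, i], "numeric", 12, size = 4, endian = "little")
    }, numeric(12))
    tri <- t(tri) # n x 12: normal, v1, v2, v3
    verts <- rbind(tri[, 4:6], tri[, 7:9], tri[, 10:12])
    ord <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]
    faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
    return(list(vertices = verts, faces = faces))
  }
  # ASCII
  txt <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0)
    stop("unreadable STL file (neither valid binary nor ASCII): ", path)
  nums <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p[2:4]))
    if (any(is.na(v))) stop("malformed ASCII STL vertex line")
    v
  }))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  list(vertices = nums, faces = faces)
}

read_ply_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3 || txt[1] != "ply") stop("not a PLY file: ", path)
  end <- match("end_header", txt)
  if (is.na(end)) stop("malformed PLY header")
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", txt, value = TRUE)))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", txt, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1) stop("malformed PLY header")
  body <- txt[(end + 1):length(txt)]
  vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vl, function(p) as.numeric(p[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fl, function(p) {
    if (as.integer(p[1]) != 3L) stop("only triangle PLY faces are supported")
    as.integer(p[2:4]) + 1L
  }))
  list(vertices = verts, faces = faces)
}

#' Write a triangle mesh to STL
#'
#' @param mesh an [new_mesh()] object.
#' @param path output path.
#' @param ascii write ASCII STL instead of binary (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "av_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, .Machine$double.eps)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- t(cbind(nrm, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]))
    for (i in seq_len(nrow(f))) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

#' Construct a landmark set
#'
#' @param points named list of length-3 numeric coordinates, or an n x 3
#'   matrix with rownames.
#' @return An object of class `av_landmarks` holding a named n x 3 matrix.
#' @export
new_landmarks <- function(points) {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("landmarks must be 3D points")
  if (is.null(rownames(points)) || any(rownames(points) == ""))
    stop("landmarks must be named")
  if (!all(is.finite(points))) stop("non-finite landmark coordinate")
  structure(list(points = points), class = "av_landmarks")
}

#' @export
print.av_landmarks <- function(x, ...) {
  cat(sprintf("<landmarks> %d points: %s\n", nrow(x$points),
              paste(rownames(x$points), collapse = ", ")))
  invisible(x)
}

#' Get a named landmark
#'
#' @param landmarks an `av_landmarks`.
#' @param name landmark name (e.g. `"ASISL"`).
#' @return length-3 numeric coordinate; errors if absent.
#' @export
landmark <- function(landmarks, name) {
  stopifnot(inherits(landmarks, "av_landmarks"))
  if (!name %in% rownames(landmarks$points))
    stop("required landmark missing: ", name)
  landmarks$points[name, ]
}

has_landmark <- function(landmarks, name) name %in% rownames(landmarks$points)

#' Read landmarks from JSON
#'
#' Expects a JSON object mapping landmark names (ASISL, ASISR, PT, FHC_L, ...)
#' to `[x, y, z]` arrays in mm. On duplicate keys the last occurrence wins
#' (with a warning). Unknown names are preserved.
#'
#' @param path path to a JSON file.
#' @return An `av_landmarks`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(lst) || is.null(names(lst)) || length(lst) == 0)
    stop("landmark file must be a JSON object of name -> [x, y, z]")
  if (anyDuplicated(names(lst))) {
    warning("duplicate landmark names; last occurrence wins")
    lst <- lst[!duplicated(names(lst), fromLast = TRUE)]
  }
  bad <- vapply(lst, function(p) !(is.numeric(p) && length(p) == 3 && all(is.finite(p))),
                logical(1))
  if (any(bad))
    stop("landmark(s) not finite 3D points: ", paste(names(lst)[bad], collapse = ", "))
  new_landmarks(lst)
}

#' Write landmarks to JSON
#' @param landmarks an `av_landmarks`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "av_landmarks"))
  lst <- lapply(seq_len(nrow(landmarks$points)),
                function(i) unname(landmarks$points[i, ]))
  names(lst) <- rownames(landmarks$points)
  jsonlite::write_json(lst, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Write measurement results to CSV
#'
#' One row per hemipelvis with a deterministic column order:
#' `id, side, av3d, av2d_stem, av2d_tallroth, lambda, rho, delta`.
#' Measurements that were not taken are `NA`. `delta` is recomputed as
#' `av3d - av2d_stem` where both are present.
#'
#' @param results a data frame of AV results (e.g. rows from [compute_av3d()]
#'   / [compute_av2d()] bound together, with an `id` column), or a list of
#'   such rows.
#' @param path output CSV path.
#' @return the written tibble, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.list(results) && !is.data.frame(results))
    results <- dplyr::bind_rows(results)
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a non-empty collection")
  tb <- tibble::as_tibble(results)
  if (!"id" %in% names(tb)) tb$id <- seq_len(nrow(tb))
  if ("method" %in% names(tb) && "angle_deg" %in% names(tb)) {
    tb <- tb |>
      dplyr::select(dplyr::any_of(c("id", "side", "method", "angle_deg",
                                    "lambda_deg", "rho_deg"))) |>
      tidyr::pivot_wider(names_from = "method", values_from = "angle_deg")
  }
  for (col in c("av3d", "av2d_stem", "av2d_tallroth", "lambda_deg", "rho_deg", "side"))
    if (!col %in% names(tb)) tb[[col]] <- NA
  out <- tibble::tibble(
    id = tb$id,
    side = tb$side,
    av3d = tb$av3d,
    av2d_stem = tb$av2d_stem,
    av2d_tallroth = tb$av2d_tallroth,
    lambda = tb$lambda_deg,
    rho = tb$rho_deg,
    delta = tb$av3d - tb$av2d_stem
  )
  readr::write_csv(out, path)
  invisible(out)
}
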