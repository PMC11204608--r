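#' Triangle mesh
#'
#' Constructs the package's universal surface representation: an `N x 3`
#' matrix of vertex coordinates in millimetres and an `M x 3` integer matrix
#' of 1-based face indices.
#'
#' @param vertices numeric matrix (`N x 3`), mm.
#' @param faces integer matrix (`M x 3`), 1-based indices into `vertices`.
#' @return an object of class `TriangleMesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!all(is.finite(vertices))) stop("mesh vertices must be finite")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "TriangleMesh")
}

#' @export
print.TriangleMesh <- function(x, ...) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices)) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

is_mesh <- function(x) inherits(x, "TriangleMesh")

stopifnot_mesh <- function(x) {
  if (!is_mesh(x)) stop("expected a TriangleMesh")
  if (nrow(x$faces) == 0L) stop("mesh is empty")
  invisible(x)
}

#' Per-face areas, normals and centroids
#'
#' @param mesh a `TriangleMesh`.
#' @return `face_areas`: numeric vector (mm^2); `face_normals`: unit normal
#'   matrix; `face_centroids`: `M x 3` matrix of triangle centroids.
#' @export
face_areas <- function(mesh) {
  cr <- .face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

.face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
        ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
        ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  cr <- .face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' @rdname face_areas
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Integral mesh properties
#'
#' Surface area as the sum of triangle areas; enclosed volume and solid
#' centroid by the divergence theorem over signed origin tetrahedra (exact
#' for closed, consistently oriented meshes).
#'
#' @param mesh a `TriangleMesh`.
#' @param signed for `mesh_volume`, return the signed value (negative for an
#'   inward-oriented mesh) instead of the absolute value.
#' @return area in mm^2, volume in mm^3, centroid as length-3 vector (mm).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
          a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
          a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  vol <- sum(det6) / 6
  if (signed) vol else abs(vol)
}

#' @rdname mesh_area
#' @export
mesh_solid_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
          a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
          a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  vol <- sum(det6) / 6
  if (abs(vol) < 1e-12) stop("mesh encloses no volume")
  ctr <- colSums((a + b + c3) / 4 * det6 / 6) / vol
  unname(ctr)
}

# undirected edge table: one row per half-edge, cols (vmin, vmax)
.mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Mesh topology checks
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces; orientation is consistent when each shared edge is traversed once
#' in each direction.
#'
#' @param mesh a `TriangleMesh`.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  e <- .mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @rdname is_watertight
#' @export
is_consistently_oriented <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  !any(duplicated(key))
}

#' Boundary loops of an open mesh
#'
#' @param mesh a `TriangleMesh`.
#' @return list of integer vectors, each an ordered closed loop of vertex
#'   indices along a boundary (edges used by exactly one face).
#' @export
boundary_loops <- function(mesh) {
  f <- mesh$faces
  e_dir <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e_dir[, 1], e_dir[, 2]), pmax(e_dir[, 1], e_dir[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (!length(bkey)) return(list())
  bd <- e_dir[key %in% bkey, , drop = FALSE]
  nxt <- stats::setNames(bd[, 2], as.character(bd[, 1]))
  loops <- list()
  used <- character(0)
  for (s in as.character(bd[, 1])) {
    if (s %in% used) next
    loop <- integer(0)
    cur <- s
    repeat {
      if (cur %in% used || !(cur %in% names(nxt))) break
      used <- c(used, cur)
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == s) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Weld coincident vertices and drop degenerate faces
#'
#' Vertices closer than `tol` are merged (grid rounding); faces that collapse
#' to fewer than three distinct vertices and exact duplicate faces are
#' removed, as are unreferenced vertices.
#'
#' @param mesh a `TriangleMesh`.
#' @param tol welding tolerance in mm.
#' @return a `TriangleMesh`.
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  vnew <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  # drop duplicate faces irrespective of rotation
  fs <- t(apply(f, 1, sort))
  f <- f[!duplicated(paste(fs[, 1], fs[, 2], fs[, 3])), , drop = FALSE]
  drop_unused_vertices(triangle_mesh(vnew, f))
}

#' @rdname weld_vertices
#' @export
drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.integer(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(map[mesh$faces], ncol = 3))
}

#' Connected components of a mesh
#'
#' Labels faces by connected component (faces joined through shared
#' vertices).
#'
#' @param mesh a `TriangleMesh`.
#' @return integer vector of component labels, one per face.
#' @export
mesh_components <- function(mesh) {
  stopifnot_mesh(mesh)
  cpp_face_components(mesh$faces, nrow(mesh$vertices))
}

#' Extract a sub-mesh from a face subset
#'
#' @param mesh a `TriangleMesh`.
#' @param face_idx integer indices of faces to keep.
#' @return a `TriangleMesh` with unreferenced vertices dropped.
#' @export
submesh <- function(mesh, face_idx) {
  drop_unused_vertices(
    triangle_mesh(mesh$vertices, mesh$faces[face_idx, , drop = FALSE]))
}

#' Repair global orientation
#'
#' Flips all faces when the signed volume is negative so that normals point
#' outward.  Issues a warning when a flip was needed.
#'
#' @param mesh a closed `TriangleMesh`.
#' @return a `TriangleMesh` with positive signed volume.
#' @export
orient_outward <- function(mesh) {
  if (mesh_volume(mesh, signed = TRUE) < 0) {
    warning("mesh was inward-oriented; flipping faces")
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  }
  mesh
}

#' Sample points uniformly by area on a mesh surface
#'
#' Faces are chosen with probability proportional to area; points are placed
#' with uniform barycentric coordinates (square-root warping).  Uses the
#' current RNG state.
#'
#' @param mesh a `TriangleMesh`.
#' @param n number of points.
#' @return `n x 3` matrix of surface points (attribute `face` holds the face
#'   index of each sample).
#' @export
sample_surface <- function(mesh, n) {
  stopifnot_mesh(mesh)
  ar <- face_areas(mesh)
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = ar)
  v <- mesh$vertices; f <- mesh$faces[fi, , drop = FALSE]
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  p <- v[f[, 1], , drop = FALSE] * w1 + v[f[, 2], , drop = FALSE] * w2 +
    v[f[, 3], , drop = FALSE] * w3
  attr(p, "face") <- fi
  p
}

#' Closest points on a mesh surface
#'
#' Exact point-to-surface projection (triangle interior, edge or vertex),
#' accelerated by a uniform spatial grid.
#'
#' @param points `n x 3` matrix of query points.
#' @param mesh a `TriangleMesh`.
#' @return list with `distance` (unsigned, mm), `point` (`n x 3` closest
#'   surface points) and `face` (1-based face index).
#' @export
closest_on_mesh <- function(points, mesh) {
  stopifnot_mesh(mesh)
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_closest_points(points, mesh$vertices, mesh$faces)
}

#' Apply a rigid (or general affine) map to mesh vertices
#'
#' @param mesh a `TriangleMesh`.
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector (mm).
#' @return the transformed `TriangleMesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, -as.numeric(translation))
  triangle_mesh(v, mesh$faces)
}

#' Mirror a mesh about the sagittal (z = 0) plane
#'
#' Faces are re-wound so the surface stays outward-oriented.
#'
#' @param mesh a `TriangleMesh`.
#' @return the mirrored `TriangleMesh`.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 3] <- -v[, 3]
  triangle_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE])
}
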