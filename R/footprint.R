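# Footprint tracing and per-attachment morphometry: contact-area selection
# on the bone surface, area, centroid, best-fit plane, breakthrough point
# and the subdivision rules used for multi-part attachments.

#' Trace the paint contact area onto the bone surface
#'
#' Selects bone faces whose centroid lies within `epsilon` of the paint
#' surface (the automated analogue of on-screen manual tracing).  Faces
#' whose offset from the paint is not aligned with the paint surface normal
#' are rejected (orientation gating): this stops the selection from
#' spilling sideways past the paint rim by up to `epsilon`, which would
#' otherwise dilate the footprint by a perimeter ring.  Connected
#' components smaller than 5% of the largest selected component (by area)
#' are dropped as spurious.
#'
#' @param bone,paint `TriangleMesh` objects in a common frame.
#' @param epsilon tracing distance in mm (default 0.5, the scale of
#'   segmentation deviation).
#' @param normal_gate minimum |cosine| between the offset direction and the
#'   nearest paint-face normal for faces farther than `0.1` mm; 0 disables
#'   gating.
#' @param name,role attachment labels carried into the result.
#' @return an object of class `Footprint`; see [footprint()].
#' @export
trace_contact_area <- function(bone, paint, epsilon = 0.5, normal_gate = 0.9,
                               name = "attachment", role = "origin") {
  stopifnot_mesh(bone); stopifnot_mesh(paint)
  if (epsilon <= 0) stop("epsilon must be positive")
  fc <- face_centroids(bone)
  cand <- .bbox_candidates(fc, paint, epsilon)
  sel <- integer(0)
  if (length(cand)) {
    d <- .trace_distance(fc[cand, , drop = FALSE], paint, normal_gate)
    sel <- cand[d <= epsilon]
  }
  if (!length(sel)) stop("no bone face lies within epsilon of the paint")
  sub <- submesh(bone, sel)
  comp <- mesh_components(sub)
  ar <- tapply(face_areas(sub), comp, sum)
  keep_comp <- as.integer(names(ar)[ar >= 0.05 * max(ar)])
  sel <- sel[comp %in% keep_comp]
  footprint(bone, sel, name = name, role = role)
}

#' Construct a footprint from a bone-face subset
#'
#' Computes the derived quantities: area (face-area sum), area-weighted
#' centroid, best-fit plane through the centroid (normal oriented outward
#' from the bone) and the breakthrough point.
#'
#' @param bone the host `TriangleMesh`.
#' @param face_idx indices of the bone faces forming the footprint.
#' @param name,role attachment labels (`role`: `"origin"` or `"insertion"`).
#' @return an object of class `Footprint`: `submesh`, `face_ids`, `area`
#'   (mm^2), `centroid`, `plane` (list `point`, `normal`),
#'   `breakthrough_point`, `fallback` (logical), `attachment_name`,
#'   `attachment_role`.
#' @export
footprint <- function(bone, face_idx, name = "attachment", role = "origin") {
  if (!length(face_idx)) stop("footprint has no faces")
  sub <- submesh(bone, face_idx)
  ar <- face_areas(sub)
  if (sum(ar) <= 0) stop("footprint has zero area")
  ctr <- footprint_centroid_faces(sub)
  outward <- colSums(face_normals(sub) * ar)
  pl <- .fit_plane(sub, ctr, outward)
  bt <- .breakthrough(sub, ctr, pl$normal)
  structure(list(submesh = sub, face_ids = as.integer(face_idx),
                 area = sum(ar), centroid = ctr, plane = pl,
                 breakthrough_point = bt$point, fallback = bt$fallback,
                 attachment_name = name, attachment_role = role),
            class = "Footprint")
}

#' @export
print.Footprint <- function(x, ...) {
  cat(sprintf("Footprint '%s' (%s): %.1f mm^2, %d faces%s\n",
              x$attachment_name, x$attachment_role, x$area,
              nrow(x$submesh$faces),
              if (x$fallback) ", breakthrough by fallback" else ""))
  invisible(x)
}

# distance from points to the paint surface, with misaligned offsets
# (sideways of the paint rim) pushed to Inf
.trace_distance <- function(points, paint, normal_gate) {
  cp <- cpp_closest_points(points, paint$vertices, paint$faces)
  d <- cp$distance
  if (normal_gate > 0) {
    off <- points - cp$point
    nn <- face_normals(paint)[cp$face, , drop = FALSE]
    align <- abs(rowSums(off * nn)) / pmax(d, 1e-12)
    d[d > 0.1 & align < normal_gate] <- Inf
  }
  d
}

# indices of points inside the mesh bbox inflated by eps (cheap prefilter
# for proximity tracing)
.bbox_candidates <- function(points, mesh, eps) {
  lo <- apply(mesh$vertices, 2, min) - eps
  hi <- apply(mesh$vertices, 2, max) + eps
  which(points[, 1] >= lo[1] & points[, 1] <= hi[1] &
          points[, 2] >= lo[2] & points[, 2] <= hi[2] &
          points[, 3] >= lo[3] & points[, 3] <= hi[3])
}

# area-weighted mean of face centroids
footprint_centroid_faces <- function(mesh) {
  ar <- face_areas(mesh)
  as.numeric(colSums(face_centroids(mesh) * ar) / sum(ar))
}

#' Footprint centroid
#'
#' Area-weighted mean of the face centroids of the footprint sub-mesh.
#'
#' @param fp a `Footprint` (or a bare `TriangleMesh`).
#' @return length-3 point (mm).
#' @export
footprint_centroid <- function(fp) {
  mesh <- if (is_mesh(fp)) fp else fp$submesh
  stopifnot_mesh(mesh)
  footprint_centroid_faces(mesh)
}

.fit_plane <- function(mesh, ctr, outward) {
  ar <- face_areas(mesh)
  fc <- face_centroids(mesh)
  X <- sweep(fc, 2, ctr) * sqrt(ar)
  C <- crossprod(X)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[2] < 1e-9 * max(eg$values[1], 1e-12))
    stop("footprint faces are collinear; best-fit plane is degenerate")
  n <- eg$vectors[, 3]
  if (sum(n * outward) < 0) n <- -n
  list(point = ctr, normal = as.numeric(n))
}

#' Best-fit plane of a footprint
#'
#' Plane through the footprint centroid minimizing the area-weighted squared
#' orthogonal distance of face centroids; the normal is the eigenvector of
#' the smallest eigenvalue of the area-weighted covariance, oriented outward
#' from the bone (along the mean face normal).
#'
#' @param fp a `Footprint`.
#' @return list with `point` and unit `normal`.
#' @export
best_fit_plane <- function(fp) {
  if (inherits(fp, "Footprint")) return(fp$plane)
  stopifnot_mesh(fp)
  ar <- face_areas(fp)
  if (sum(ar) <= 0)
    stop("footprint has zero total area; best-fit plane is degenerate")
  ctr <- footprint_centroid_faces(fp)
  outward <- colSums(face_normals(fp) * ar)
  .fit_plane(fp, ctr, outward)
}

# all intersections of the line ctr + t n with the mesh (Moller-Trumbore,
# vectorized over faces); returns signed t values
.line_mesh_hits <- function(mesh, orig, dir) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- sweep(a, 2, orig, FUN = function(x, y) y - x)  # orig - a
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / det
  t <- rowSums(e2 * q) / det
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9
  t[hit]
}

.breakthrough <- function(mesh, ctr, normal) {
  t <- .line_mesh_hits(mesh, ctr, normal)
  if (length(t)) {
    tb <- t[which.min(abs(t))]
    list(point = as.numeric(ctr + tb * normal), fallback = FALSE)
  } else {
    cp <- cpp_closest_points(matrix(ctr, 1, 3), mesh$vertices, mesh$faces)
    list(point = as.numeric(cp$point[1, ]), fallback = TRUE)
  }
}

#' Breakthrough point of a footprint
#'
#' Pierces the footprint surface with the line through the centroid along
#' the best-fit-plane normal and returns the intersection nearest the
#' centroid.  When the line misses the surface (e.g. an annular footprint),
#' the nearest surface point to the centroid is returned and flagged.
#'
#' @param fp a `Footprint`.
#' @return length-3 point (mm) with attribute `fallback`.
#' @export
breakthrough_point <- function(fp) {
  if (inherits(fp, "Footprint")) {
    out <- fp$breakthrough_point
    attr(out, "fallback") <- fp$fallback
    return(out)
  }
  stopifnot_mesh(fp)
  ctr <- footprint_centroid_faces(fp)
  pl <- best_fit_plane(fp)
  bt <- .breakthrough(fp, ctr, pl$normal)
  out <- bt$point
  attr(out, "fallback") <- bt$fallback
  out
}

# --- subdivision ------------------------------------------------------------

#' Subdivision rule specification
#'
#' @param rule one of `"linear_thirds"`, `"plane_split"`,
#'   `"vastus_intermedius_2x3"`, `"thinnest_part"`.
#' @param axis_points optional 2 x 3 matrix: proximal and distal chord
#'   endpoints (defaults to the sub-mesh vertices extremal along `axis`).
#' @param plane_points 3 x 3 matrix defining a splitting plane
#'   (`plane_split` only).
#' @param axis fallback proximal-distal direction (default the frame y
#'   axis).
#' @return an object of class `SubdivisionSpec`.
#' @export
subdivision_spec <- function(rule = c("linear_thirds", "plane_split",
                                      "vastus_intermedius_2x3",
                                      "thinnest_part"),
                             axis_points = NULL, plane_points = NULL,
                             axis = c(0, 1, 0)) {
  rule <- match.arg(rule)
  if (rule == "plane_split") {
    if (is.null(plane_points)) stop("plane_split needs plane_points")
    plane_points <- matrix(as.numeric(plane_points), ncol = 3)
    if (nrow(plane_points) != 3L) stop("plane_points must be 3 x 3")
  }
  if (!is.null(axis_points)) {
    axis_points <- matrix(as.numeric(axis_points), ncol = 3)
    if (nrow(axis_points) != 2L) stop("axis_points must be 2 x 3")
  }
  structure(list(rule = rule, axis_points = axis_points,
                 plane_points = plane_points, axis = as.numeric(axis)),
            class = "SubdivisionSpec")
}

.chord_endpoints <- function(fp, spec) {
  if (!is.null(spec$axis_points))
    return(list(p = spec$axis_points[1, ], d = spec$axis_points[2, ]))
  v <- fp$submesh$vertices
  proj <- as.numeric(v %*% normalize(spec$axis))
  list(p = v[which.max(proj), ], d = v[which.min(proj), ])
}

# signed side of face centroids w.r.t. a plane
.face_side <- function(fp, point, normal) {
  as.numeric(sweep(face_centroids(fp$submesh), 2, point) %*% normalize(normal))
}

.child <- function(fp, local_faces, suffix) {
  if (!length(local_faces)) stop("subdivision produced an empty part")
  footprint(fp$submesh, local_faces,
            name = paste0(fp$attachment_name, suffix),
            role = fp$attachment_role)
}

.cut_thirds <- function(fp, p, d) {
  u <- normalize(d - p)
  t <- as.numeric(sweep(face_centroids(fp$submesh), 2, p) %*% u)
  L <- vnorm(d - p)
  list(which(t < L / 3), which(t >= L / 3 & t < 2 * L / 3), which(t >= 2 * L / 3))
}

#' Subdivide a footprint
#'
#' `linear_thirds`: three parts cut by two planes perpendicular to the
#' proximal-distal chord at 1/3 and 2/3 of its length.  `plane_split`: two
#' parts by the plane through three given points.
#' `vastus_intermedius_2x3`: six parts (a halving plane containing the chord
#' and the footprint normal, crossed with length-wise thirds).
#' `thinnest_part`: two parts cut where the footprint is narrowest across
#' the chord.  Faces are assigned whole by face-centroid side, so child
#' areas sum exactly to the parent area.
#'
#' @param fp a `Footprint`.
#' @param spec a `SubdivisionSpec`.
#' @return list of `Footprint` objects.
#' @export
subdivide <- function(fp, spec) {
  if (!inherits(fp, "Footprint")) stop("expected a Footprint")
  if (!inherits(spec, "SubdivisionSpec")) stop("expected a SubdivisionSpec")
  ends <- if (spec$rule != "plane_split") .chord_endpoints(fp, spec) else NULL
  if (spec$rule == "linear_thirds") {
    parts <- .cut_thirds(fp, ends$p, ends$d)
    out <- lapply(seq_along(parts), function(i)
      .child(fp, parts[[i]], paste0("_", i, "of3")))
  } else if (spec$rule == "plane_split") {
    pp <- spec$plane_points
    n <- pracma_cross(pp[2, ] - pp[1, ], pp[3, ] - pp[1, ])
    if (vnorm(n) < 1e-9) stop("plane points are collinear")
    s <- .face_side(fp, pp[1, ], n)
    out <- list(.child(fp, which(s >= 0), "_a"),
                .child(fp, which(s < 0), "_b"))
  } else if (spec$rule == "vastus_intermedius_2x3") {
    u <- normalize(ends$d - ends$p)
    nrm <- fp$plane$normal
    hn <- pracma_cross(u, nrm)
    if (vnorm(hn) < 1e-9) stop("chord is parallel to the footprint normal")
    s <- .face_side(fp, ends$p, hn)
    thirds <- .cut_thirds(fp, ends$p, ends$d)
    out <- list()
    for (i in seq_along(thirds)) {
      for (half in c("m", "l")) {
        idx <- if (half == "m") intersect(thirds[[i]], which(s >= 0))
               else intersect(thirds[[i]], which(s < 0))
        out[[length(out) + 1L]] <-
          .child(fp, idx, paste0("_", half, i))
      }
    }
  } else {  # thinnest_part
    u <- normalize(ends$d - ends$p)
    fc <- face_centroids(fp$submesh)
    t <- as.numeric(sweep(fc, 2, ends$p) %*% u)
    L <- vnorm(ends$d - ends$p)
    perp <- sweep(fc, 2, ends$p) - outer(t, u)
    wpos <- sqrt(rowSums(perp^2))
    cand <- seq(0.15 * L, 0.85 * L, length.out = 57L)
    width <- vapply(cand, function(tc) {
      inb <- abs(t - tc) <= L * 0.04
      if (!any(inb)) return(Inf)
      max(wpos[inb])
    }, numeric(1))
    tc <- cand[which.min(width)]
    out <- list(.child(fp, which(t < tc), "_a"),
                .child(fp, which(t >= tc), "_b"))
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resolve overlapping paint marks across attachments
#'
#' Traces every paint surface against the bone and assigns faces claimed by
#' more than one attachment to the nearer paint surface; exact ties go to
#' the lexicographically first attachment name.
#'
#' @param bone the host `TriangleMesh`.
#' @param paints named list of paint `TriangleMesh` objects.
#' @param epsilon tracing distance (mm).
#' @param normal_gate orientation gate, as in [trace_contact_area()].
#' @param roles optional named character vector of attachment roles.
#' @return named list of `Footprint` objects.
#' @export
trace_footprints <- function(bone, paints, epsilon = 0.5, normal_gate = 0.9,
                             roles = NULL) {
  stopifnot_mesh(bone)
  nms <- sort(names(paints))
  fc <- face_centroids(bone)
  D <- matrix(Inf, nrow(fc), length(nms), dimnames = list(NULL, nms))
  for (j in seq_along(nms)) {
    p <- paints[[nms[j]]]
    cand <- .bbox_candidates(fc, p, epsilon)
    if (length(cand))
      D[cand, j] <- .trace_distance(fc[cand, , drop = FALSE], p, normal_gate)
  }
  within <- D <= epsilon
  owner <- max.col(-D, ties.method = "first")  # nearest paint, first name wins
  out <- list()
  for (j in seq_along(nms)) {
    idx <- which(within[, j] & owner == j)
    if (!length(idx)) next
    role <- if (!is.null(roles) && nms[j] %in% names(roles))
      roles[[nms[j]]] else "origin"
    fp <- footprint(bone, idx, name = nms[j], role = role)
    # drop spurious slivers exactly as single-patch tracing does
    comp <- mesh_components(fp$submesh)
    ar <- tapply(face_areas(fp$submesh), comp, sum)
    keep_comp <- as.integer(names(ar)[ar >= 0.05 * max(ar)])
    if (length(keep_comp) < length(ar))
      fp <- footprint(bone, idx[comp %in% keep_comp], name = nms[j], role = role)
    out[[nms[j]]] <- fp
  }
  out
}
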