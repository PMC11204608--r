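# Coherent-model construction: rigid alignment of repeat-scan surfaces,
# point-to-surface deviation analysis, merging, hole filling and smoothing.

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @return an object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param transform,a,b `RigidTransform` objects.
#' @param points `n x 3` matrix.
#' @export
rt_apply <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' @rdname rigid_transform
#' @export
rt_compose <- function(a, b) {
  # (a o b): apply b first, then a
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
rt_invert <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*% transform$translation))
}

#' @rdname rigid_transform
#' @export
rt_angle_deg <- function(transform) {
  acos(pmin(pmax((sum(diag(transform$rotation)) - 1) / 2, -1), 1)) * 180 / pi
}

# least-squares rigid fit (Kabsch) mapping point set A onto B
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cb - as.numeric(R %*% ca))
}

# deterministic surface subsample used for ICP correspondences
.icp_samples <- function(mesh, n) {
  nv <- nrow(mesh$vertices)
  idx <- if (nv <= n) seq_len(nv) else round(seq(1, nv, length.out = n))
  mesh$vertices[idx, , drop = FALSE]
}

#' Rigid registration of two surfaces (landmark-initialized ICP)
#'
#' When landmark pairs are given, a least-squares rigid fit initializes the
#' registration; iterative closest point refinement then minimizes mean
#' point-to-surface distance of a deterministic vertex subsample of the
#' moving mesh against the fixed surface.
#'
#' @param moving,fixed `TriangleMesh` objects.
#' @param init_landmarks optional list with `moving` and `fixed`, matched
#'   `k x 3` matrices (k >= 3, non-collinear).
#' @param max_iter iteration cap.
#' @param tol convergence threshold on mean-distance improvement (mm).
#' @param n_samples number of moving-surface sample points.
#' @return a `RigidTransform` mapping `moving` into the frame of `fixed`;
#'   attribute `mean_distance` holds the final mean point-to-surface
#'   distance.
#' @export
rigid_align <- function(moving, fixed, init_landmarks = NULL,
                        max_iter = 100L, tol = 1e-4, n_samples = 2000L) {
  stopifnot_mesh(moving); stopifnot_mesh(fixed)
  tf <- rigid_transform()
  if (!is.null(init_landmarks)) {
    A <- matrix(as.numeric(init_landmarks$moving), ncol = 3)
    B <- matrix(as.numeric(init_landmarks$fixed), ncol = 3)
    if (nrow(A) < 3L || nrow(A) != nrow(B))
      stop("need at least 3 matched landmark pairs")
    svA <- svd(sweep(A, 2, colMeans(A)))
    if (svA$d[2] < 1e-6 * max(svA$d[1], 1e-12))
      stop("landmarks are collinear; registration is degenerate")
    tf <- kabsch(A, B)
  }
  P0 <- .icp_samples(moving, n_samples)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    P <- rt_apply(tf, P0)
    cp <- cpp_closest_points(P, fixed$vertices, fixed$faces)
    m <- mean(cp$distance)
    if (is.finite(prev) && prev - m < tol) { prev <- m; break }
    prev <- m
    tf <- rt_compose(kabsch(P, cp$point), tf)
  }
  attr(tf, "mean_distance") <- prev
  tf
}

#' Point-to-surface deviation of one mesh from a reference
#'
#' Samples `n_samples` points uniformly by area on the test surface and
#' measures the unsigned distance of each to the nearest point of the
#' reference surface (triangle interior, edge or vertex).  Summaries use the
#' population standard deviation.
#'
#' @param test,reference `TriangleMesh` objects in a common frame.
#' @param n_samples number of surface samples.
#' @return an object of class `DeviationResult`: `distances` (mm), `mean`,
#'   `std`, `max`, `n`.
#' @export
deviation_analysis <- function(test, reference, n_samples = 10000L) {
  stopifnot_mesh(test); stopifnot_mesh(reference)
  P <- sample_surface(test, n_samples)
  d <- cpp_closest_points(P, reference$vertices, reference$faces)$distance
  structure(list(distances = d, mean = mean(d),
                 std = sqrt(mean((d - mean(d))^2)), max = max(d),
                 n = n_samples),
            class = "DeviationResult")
}

#' @export
print.DeviationResult <- function(x, ...) {
  cat(sprintf("DeviationResult: mean %.3f mm, STD %.3f mm, max %.3f mm (n = %d)\n",
              x$mean, x$std, x$max, x$n))
  invisible(x)
}

# Taubin lambda/mu smoothing on a vertex adjacency; boundary vertices fixed
taubin_smooth <- function(mesh, iters = 10L, lambda = 0.5, mu = -0.53) {
  if (iters <= 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  e <- unique(rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
                    f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(v), nrow(v)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  # keep open boundaries pinned so shells do not curl
  bl <- unlist(boundary_loops(mesh))
  free <- rep(TRUE, nrow(v))
  if (length(bl)) free[bl] <- FALSE
  step <- function(vv, w) {
    lap <- as.matrix(A %*% vv) / deg - vv
    vv[free, ] <- vv[free, ] + w * lap[free, , drop = FALSE]
    vv
  }
  for (i in seq_len(iters)) { v <- step(v, lambda); v <- step(v, mu) }
  out <- triangle_mesh(v, f)
  # shrink-compensation: rescale about the solid centroid to conserve volume
  if (is_watertight(mesh)) {
    v0 <- mesh_volume(mesh); v1 <- mesh_volume(out)
    if (v1 > 0 && abs(v1 - v0) / v0 > 1e-6) {
      ctr <- mesh_solid_centroid(out)
      s <- (v0 / v1)^(1 / 3)
      out$vertices <- sweep(sweep(out$vertices, 2, ctr), 2, -ctr / s) * s
    }
  }
  out
}

# triangulate boundary loops with <= max_edges edges by a centroid fan
fill_holes <- function(mesh, max_edges = 200L) {
  loops <- boundary_loops(mesh)
  if (!length(loops)) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (lp in loops) {
    if (length(lp) > max_edges) next
    ctr <- colMeans(v[lp, , drop = FALSE])
    cid <- nrow(v) + 1L
    v <- rbind(v, ctr)
    nl <- length(lp)
    # boundary edges run lp[i] -> lp[i+1] as seen from existing faces; wind
    # the fan the opposite way to keep orientation consistent
    f <- rbind(f, cbind(lp[c(2:nl, 1)], lp, cid))
  }
  triangle_mesh(v, f)
}

#' Merge repeat-scan surfaces into one coherent model
#'
#' Concatenates pre-aligned surfaces, welds coincident vertices, removes
#' degenerate and duplicate faces, closes small holes (boundary loops up to
#' `hole_max_edges` edges) and applies Taubin smoothing with
#' shrink-compensation so the enclosed volume drifts by less than 1%.
#' A warning is issued when the result still has several connected
#' components.
#'
#' @param meshes list of `TriangleMesh` objects in a common frame.
#' @param smoothing_iters Taubin iterations (0 = none).
#' @param smoothing_lambda positive smoothing step (the shrink-correcting
#'   negative step is derived from it).
#' @param weld_tol vertex welding tolerance (mm).
#' @param hole_max_edges largest boundary loop that will be closed.
#' @return a `TriangleMesh`.
#' @export
merge_and_clean <- function(meshes, smoothing_iters = 10L,
                            smoothing_lambda = 0.5, weld_tol = 1e-6,
                            hole_max_edges = 200L) {
  if (is_mesh(meshes)) meshes <- list(meshes)
  if (!length(meshes)) stop("no meshes to merge")
  vs <- list(); fs <- list(); off <- 0L
  for (m in meshes) {
    stopifnot_mesh(m)
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  mesh <- triangle_mesh(do.call(rbind, vs), do.call(rbind, fs))
  mesh <- weld_vertices(mesh, tol = weld_tol)
  mesh <- fill_holes(mesh, max_edges = hole_max_edges)
  if (smoothing_iters > 0)
    mesh <- taubin_smooth(mesh, iters = smoothing_iters,
                          lambda = smoothing_lambda,
                          mu = -(smoothing_lambda + 0.03))
  if (length(unique(mesh_components(mesh))) > 1L)
    warning("merged mesh has multiple connected components")
  mesh
}
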