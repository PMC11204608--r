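# Shared fixtures, memoized for the test session, plus independent oracles
# implemented in plain R (kept deliberately separate from the package's
# C++ code paths).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fixture_femur <- function() fixture("femur", function()
  make_synthetic_bone("femur", seed = 1))

fixture_femur_coarse <- function() fixture("femur_coarse", function()
  make_synthetic_bone("femur", seed = 1, pitch = 1.4))

fixture_sphere20 <- function() fixture("sphere20", function()
  mesh_from_primitives(list(ctfootprint:::prim_sphere(c(0, 0, 0), 20)),
                       pitch = 1))

fixture_sphere20.5 <- function() fixture("sphere20.5", function()
  mesh_from_primitives(list(ctfootprint:::prim_sphere(c(0, 0, 0), 20.5)),
                       pitch = 1))

# 12-triangle unit cube, outward oriented
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  triangle_mesh(v, f)
}

# planar rectangular grid mesh in the z = 0 plane
grid_mesh <- function(nx = 20, ny = 20, lx = 1, ly = 1, x0 = 0, y0 = 0) {
  xs <- seq(x0, x0 + lx, length.out = nx + 1)
  ys <- seq(y0, y0 + ly, length.out = ny + 1)
  v <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1), 0)
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  f <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  triangle_mesh(v, f)
}

# parametric spherical band mesh (polar angles [psi0, psi1] about +y),
# exactly symmetric about the y axis
sphere_band_mesh <- function(r = 25, psi0 = 0, psi1 = pi / 6,
                             n_psi = 24, n_phi = 72, center = c(0, 0, 0)) {
  psis <- seq(psi0, psi1, length.out = n_psi + 1)
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-1]
  pole0 <- psi0 == 0
  rows <- list()
  for (psi in psis[if (pole0) -1 else TRUE]) {
    rows[[length(rows) + 1L]] <-
      cbind(r * sin(psi) * cos(phis), r * cos(psi), r * sin(psi) * sin(phis))
  }
  v <- do.call(rbind, rows)
  if (pole0) v <- rbind(c(0, r, 0), v)
  off <- if (pole0) 1L else 0L
  id <- function(ring, k) off + (ring - 1L) * n_phi + ((k - 1L) %% n_phi) + 1L
  f <- NULL
  n_rings <- length(rows)
  if (pole0) {
    for (k in seq_len(n_phi)) f <- rbind(f, c(1L, id(1, k + 1), id(1, k)))
  }
  for (ring in seq_len(n_rings - 1L)) for (k in seq_len(n_phi)) {
    f <- rbind(f,
               c(id(ring, k), id(ring, k + 1), id(ring + 1, k)),
               c(id(ring, k + 1), id(ring + 1, k + 1), id(ring + 1, k)))
  }
  m <- triangle_mesh(sweep(v, 2, -center), f)
  # orient outward (normals away from the center)
  nrm <- face_normals(m)
  fc <- face_centroids(m)
  out <- rowSums(nrm * sweep(fc, 2, center)) > 0
  mm <- m$faces
  mm[!out, ] <- mm[!out, c(1, 3, 2)]
  triangle_mesh(m$vertices, mm)
}

# independent closest-point oracle in plain R: for every face enumerate all
# candidate closest points (vertices, clamped edge projections, and the
# plane projection when its barycentric coordinates are valid) and take the
# global minimum.  No region logic, so no region-logic bugs.
brute_closest_dist <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  seg_d2 <- function(p, s0, s1) {
    d <- s1 - s0
    l2 <- pmax(rowSums(d^2), 1e-300)
    t <- pmin(pmax(rowSums(sweep(s0, 2, p, function(x, y) y - x) * d) / l2, 0), 1)
    rowSums((s0 + d * t - matrix(p, nrow(s0), 3, byrow = TRUE))^2)
  }
  apply(matrix(as.numeric(points), ncol = 3), 1, function(p) {
    best2 <- pmin(seg_d2(p, a, b), seg_d2(p, b, c3), seg_d2(p, c3, a))
    # interior projection via barycentric coordinates
    ab <- b - a; ac <- c3 - a
    ap <- sweep(a, 2, p, function(x, y) y - x)
    d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
    d20 <- rowSums(ap * ab); d21 <- rowSums(ap * ac)
    den <- d00 * d11 - d01^2
    ok <- den > 1e-300
    vv <- ifelse(ok, (d11 * d20 - d01 * d21) / den, -1)
    ww <- ifelse(ok, (d00 * d21 - d01 * d20) / den, -1)
    inside <- ok & vv >= 0 & ww >= 0 & (vv + ww) <= 1
    if (any(inside)) {
      q <- a[inside, , drop = FALSE] + vv[inside] * ab[inside, , drop = FALSE] +
        ww[inside] * ac[inside, , drop = FALSE]
      best2[inside] <- pmin(best2[inside],
                            rowSums(sweep(q, 2, p)^2))
    }
    sqrt(min(best2))
  })
}

# population mean / STD by an independent two-pass formula
pop_oracle <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, std = sqrt(sum((x - m)^2) / length(x)))
}

rel_err <- function(a, b) abs(a - b) / abs(b)
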