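# Synthetic specimens: implicit-primitive phantom bones, paint patches with
# analytic ground truth, voxelized CT volumes and multi-specimen cohorts.
#
# Bones are modelled as unions of spheres and capsules.  The implicit
# representation travels with every bone so that voxelization and paint-shell
# placement are analytic rather than mesh-dependent.

# --- primitives -------------------------------------------------------------

prim_sphere <- function(center, radius, name = "sphere") {
  list(type = "sphere", center = as.numeric(center), radius = radius, name = name)
}

prim_capsule <- function(a, b, radius, name = "capsule") {
  list(type = "capsule", a = as.numeric(a), b = as.numeric(b), radius = radius,
       name = name)
}

# squared distance from points to segment a-b, plus axial parameter t (mm)
.seg_geom <- function(P, a, b) {
  d <- b - a
  L <- vnorm(d)
  u <- d / L
  rel <- sweep(P, 2, a)
  t <- as.numeric(rel %*% u)
  tc <- pmin(pmax(t, 0), L)
  cp <- outer(tc, u)
  dv <- rel - cp
  list(d = sqrt(rowSums(dv^2)), t = t, len = L, u = u)
}

prim_inside <- function(prim, P, inflate = 0) {
  if (prim$type == "sphere") {
    rowSums(sweep(P, 2, prim$center)^2) <= (prim$radius + inflate)^2
  } else {
    .seg_geom(P, prim$a, prim$b)$d <= prim$radius + inflate
  }
}

# signed distance to the primitive's own surface (<0 inside)
prim_surf_dist <- function(prim, P) {
  if (prim$type == "sphere") {
    sqrt(rowSums(sweep(P, 2, prim$center)^2)) - prim$radius
  } else {
    .seg_geom(P, prim$a, prim$b)$d - prim$radius
  }
}

prims_inside <- function(prims, P, inflate = 0) {
  ins <- rep(FALSE, nrow(P))
  for (pr in prims) ins <- ins | prim_inside(pr, P, inflate)
  ins
}

prims_bbox <- function(prims, margin = 0) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (pr in prims) {
    if (pr$type == "sphere") {
      lo <- pmin(lo, pr$center - pr$radius); hi <- pmax(hi, pr$center + pr$radius)
    } else {
      lo <- pmin(lo, pmin(pr$a, pr$b) - pr$radius)
      hi <- pmax(hi, pmax(pr$a, pr$b) + pr$radius)
    }
  }
  list(lo = lo - margin, hi = hi + margin)
}

.mirror_vec <- function(v) c(v[1], v[2], -v[3])

prim_mirror <- function(prim) {
  if (prim$type == "sphere") prim$center <- .mirror_vec(prim$center)
  else { prim$a <- .mirror_vec(prim$a); prim$b <- .mirror_vec(prim$b) }
  prim
}

# --- separable 3x3x3 box smoothing of a 3D field (zero padded) --------------

.box1 <- function(a, axis) {
  d <- dim(a)
  shift <- function(arr, by) {
    out <- array(0, d)
    n <- d[axis]
    if (by == 0) return(arr)
    src <- if (by > 0) seq_len(n - by) else seq.int(1 - by, n)
    dst <- if (by > 0) seq.int(1 + by, n) else seq_len(n + by)
    if (axis == 1) out[dst, , ] <- arr[src, , ]
    else if (axis == 2) out[, dst, ] <- arr[, src, ]
    else out[, , dst] <- arr[, , src]
    out
  }
  (shift(a, -1L) + a + shift(a, 1L)) / 3
}

smooth_field3 <- function(a, iters = 1L) {
  for (i in seq_len(iters)) for (ax in 1:3) a <- .box1(a, ax)
  a
}

# --- implicit meshing -------------------------------------------------------

#' Mesh an implicit primitive union
#'
#' Voxelizes the inside predicate on a regular grid, optionally smooths the
#' indicator field with a separable box filter (one pass markedly reduces the
#' surface-area bias of midpoint isosurfaces of binary grids), pads with
#' outside values and extracts the 0.5 isosurface by marching tetrahedra.
#'
#' @param prims list of primitives (`prim_sphere` / `prim_capsule`).
#' @param pitch grid spacing in mm.
#' @param field_smoothing number of box-smoothing passes of the indicator.
#' @return a watertight, outward-oriented `TriangleMesh`.
#' @export
mesh_from_primitives <- function(prims, pitch = 1.0, field_smoothing = 1L) {
  bb <- prims_bbox(prims, margin = 2 * pitch)
  dims <- pmax(ceiling((bb$hi - bb$lo) / pitch) + 1L, 2L)
  gx <- bb$lo[1] + (seq_len(dims[1]) - 1) * pitch
  gy <- bb$lo[2] + (seq_len(dims[2]) - 1) * pitch
  gz <- bb$lo[3] + (seq_len(dims[3]) - 1) * pitch
  # evaluate slab-wise to bound memory
  field <- array(0, dims)
  xy <- cbind(rep(gx, times = dims[2]), rep(gy, each = dims[1]))
  for (k in seq_len(dims[3])) {
    P <- cbind(xy, gz[k])
    field[, , k] <- as.numeric(prims_inside(prims, P))
  }
  if (field_smoothing > 0) field <- smooth_field3(field, field_smoothing)
  mesh_from_field(field, spacing = rep(pitch, 3), origin = bb$lo, level = 0.5)
}

# pad a scalar field with a zero shell and run marching tetrahedra
mesh_from_field <- function(field, spacing, origin, level = 0.5) {
  d <- dim(field)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  res <- cpp_marching_tets(as.numeric(pad), dim(pad), as.numeric(spacing),
                           as.numeric(origin - spacing), level)
  if (nrow(res$faces) == 0L) stop("isosurface is empty")
  triangle_mesh(res$vertices, res$faces)
}

# --- synthetic bones --------------------------------------------------------

#' Generate a synthetic bone
#'
#' Phantom bones assembled from spheres and capsules, meshed from the
#' implicit union.  The femur is laid out in its own ISB frame: origin at the
#' transepicondylar-axis (TEA) midpoint, y toward the femoral head (cranial),
#' z lateral, x anterior; defaults reproduce cohort-mean femoral
#' morphometrics (mechanical axis 405.38 mm, TEA 91.65 mm, head diameter
#' 50.93 mm, shaft diameter 35.70 mm).
#'
#' @param kind one of `"femur"`, `"tibia_fibula"`, `"patella"`, `"pelvis"`,
#'   `"generic"`.
#' @param size_params named list overriding per-kind dimensions (mm); femur
#'   accepts `length`, `head_radius`, `shaft_radius`, `tea`,
#'   `condyle_radius`, `neck_radius`.
#' @param seed integer; perturbs only non-metric shape detail so repeated
#'   calls are bit-identical.
#' @param pitch meshing grid spacing in mm.
#' @param mesh when `FALSE`, skip isosurface extraction and return only the
#'   implicit model and landmarks (used for large truth-only cohorts).
#' @return an object of class `SyntheticBone`: fields `mesh`
#'   (`TriangleMesh`), `landmarks` (named 3-vectors), `primitives`, `kind`,
#'   `side`.
#' @export
make_synthetic_bone <- function(kind = c("femur", "tibia_fibula", "patella",
                                         "pelvis", "generic"),
                                size_params = list(), seed = 1L, pitch = 0.8,
                                mesh = TRUE) {
  kind <- match.arg(kind)
  p <- size_params
  gp <- function(nm, def) if (!is.null(p[[nm]])) p[[nm]] else def
  chk <- function(x, nm) {
    if (!is.numeric(x) || x <= 0) stop("size parameter '", nm, "' must be positive")
    x
  }
  jit <- with_seed(seed, runif(4, -0.005, 0.005))
  lm <- list()
  if (kind == "femur") {
    ma <- chk(gp("length", 405.38), "length")
    rh <- chk(gp("head_radius", 25.465), "head_radius")
    rs <- chk(gp("shaft_radius", 17.85), "shaft_radius")
    tea <- chk(gp("tea", 91.65), "tea")
    rc <- chk(gp("condyle_radius", 21), "condyle_radius") * (1 + jit[1])
    rn <- chk(gp("neck_radius", 12), "neck_radius") * (1 + jit[2])
    hc <- c(0, ma, 0)
    cz <- tea / 2 - rc
    prims <- list(
      head = prim_sphere(hc, rh, "head"),
      neck = prim_capsule(c(0, ma - 1.8 * rh, 0), hc, rn, "neck"),
      shaft = prim_capsule(c(0, rc * 0.5, 0), c(0, ma - rh, 0), rs, "shaft"),
      condyle_med = prim_sphere(c(0, 0, -cz), rc, "condyle_med"),
      condyle_lat = prim_sphere(c(0, 0, cz), rc, "condyle_lat"),
      condyle_bridge = prim_capsule(c(0, 0, -cz), c(0, 0, cz), 0.8 * rc,
                                    "condyle_bridge"))
    lm <- list(head_center = hc,
               epicondyle_medial = c(0, 0, -tea / 2),
               epicondyle_lateral = c(0, 0, tea / 2),
               most_proximal = c(0, ma + rh, 0),
               most_distal = c(0, -rc, cz))
  } else if (kind == "tibia_fibula") {
    tl <- chk(gp("length", 370), "length")
    rt <- chk(gp("shaft_radius", 14), "shaft_radius")
    rp <- chk(gp("plateau_radius", 22), "plateau_radius")
    rf <- chk(gp("fibula_radius", 6), "fibula_radius") * (1 + jit[1])
    top <- c(0, -12, 0)
    prims <- list(
      plateau = prim_sphere(top, rp, "plateau"),
      tibia = prim_capsule(top, c(0, -12 - tl, 0), rt, "tibia"),
      fibula = prim_capsule(c(3, -25, 27), c(5, -20 - tl, 30), rf, "fibula"))
    lm <- list(plateau_center = top,
               fibula_head = c(3, -25, 27),
               most_proximal = top + c(0, rp, 0),
               most_distal = c(0, -12 - tl - rt, 0))
  } else if (kind == "patella") {
    rp <- chk(gp("radius", 12), "radius")
    ctr <- c(38, 8, 0)
    prims <- list(body = prim_sphere(ctr, rp, "body"))
    lm <- list(center = ctr, most_proximal = ctr + c(0, rp, 0),
               most_distal = ctr - c(0, rp, 0))
  } else if (kind == "pelvis") {
    rb <- chk(gp("radius", 30), "radius")
    ma <- chk(gp("height", 470), "height")
    c1 <- c(0, ma, -25); c2 <- c(0, ma + 40, 25)
    prims <- list(blade1 = prim_sphere(c1, rb, "blade1"),
                  blade2 = prim_sphere(c2, rb * 0.9, "blade2"),
                  bridge = prim_capsule(c1, c2, rb * 0.6, "bridge"))
    lm <- list(acetabulum = c1, most_proximal = c2 + c(0, rb, 0))
  } else {
    rg <- chk(gp("radius", 20), "radius")
    ctr <- gp("center", c(0, 0, 0))
    prims <- list(body = prim_sphere(ctr, rg, "body"))
    lm <- list(center = ctr)
  }
  mesh <- if (isTRUE(mesh)) mesh_from_primitives(prims, pitch = pitch) else NULL
  structure(list(kind = kind, side = "right", mesh = mesh,
                 landmarks = lapply(lm, as.numeric),
                 primitives = prims, pitch = pitch, seed = as.integer(seed)),
            class = "SyntheticBone")
}

#' @export
print.SyntheticBone <- function(x, ...) {
  cat(sprintf("SyntheticBone '%s' (%s side): %d primitives, %d landmarks\n",
              x$kind, x$side, length(x$primitives), length(x$landmarks)))
  print(x$mesh)
  invisible(x)
}

# --- paint patches ----------------------------------------------------------

# orthonormal frame (e1, e2) perpendicular to a unit axis u
.perp_frame <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# polygonal boundary radius theta(phi) for the star-shaped geodesic region
.poly_theta <- function(region, phi) {
  region$theta * (1 + region$amp * cos(region$k * (phi - region$phi_off)))
}

# membership of 3D points in the painted region of the host primitive
patch_membership <- function(patch, P, surf_tol = NULL) {
  prim <- patch$prim
  reg <- patch$region
  ok <- rep(TRUE, nrow(P))
  if (!is.null(surf_tol)) ok <- abs(prim_surf_dist(prim, P)) <= surf_tol
  if (patch$shape_class %in% c("cap", "polygonal")) {
    rel <- sweep(P, 2, prim$center)
    rn <- sqrt(rowSums(rel^2)); rn[rn == 0] <- 1
    ca <- as.numeric(rel %*% reg$axis) / rn
    ca <- pmin(pmax(ca, -1), 1)
    psi <- acos(ca)
    if (patch$shape_class == "cap") ok & psi <= reg$theta
    else {
      phi <- atan2(as.numeric(rel %*% reg$e2), as.numeric(rel %*% reg$e1))
      ok & psi <= .poly_theta(reg, phi)
    }
  } else {  # linear strip on a capsule shaft
    sg <- .seg_geom(P, prim$a, prim$b)
    ok <- ok & sg$t >= reg$s0 & sg$t <= reg$s0 + reg$len
    ax <- outer(sg$t, sg$u)
    rad <- sweep(P, 2, prim$a) - ax
    phi <- atan2(as.numeric(rad %*% reg$e2), as.numeric(rad %*% reg$e1))
    dphi <- abs(((phi - reg$phi0 + pi) %% (2 * pi)) - pi)
    ok & (prim$radius * dphi) <= reg$w / 2
  }
}

# analytic / quadrature ground truth for a patch region
.patch_truth <- function(shape_class, prim, reg) {
  if (shape_class == "cap") {
    r <- prim$radius
    area <- 2 * pi * r^2 * (1 - cos(reg$theta))
    centroid <- prim$center + reg$axis * r * (1 + cos(reg$theta)) / 2
    list(area = area, centroid = centroid)
  } else if (shape_class == "polygonal") {
    r <- prim$radius
    phi <- seq(0, 2 * pi, length.out = 4097L)[-1]
    th <- .poly_theta(reg, phi)
    dphi <- 2 * pi / length(phi)
    area <- r^2 * sum(1 - cos(th)) * dphi
    w_perp <- (th - sin(th) * cos(th)) / 2
    w_ax <- sin(th)^2 / 2
    cx <- r^3 * sum(cos(phi) * w_perp) * dphi
    cy <- r^3 * sum(sin(phi) * w_perp) * dphi
    cz <- r^3 * sum(w_ax) * dphi
    centroid <- prim$center +
      (cx * reg$e1 + cy * reg$e2 + cz * reg$axis) / area
    list(area = area, centroid = centroid)
  } else {
    r <- prim$radius
    u <- normalize(prim$b - prim$a)
    alpha <- reg$w / (2 * r)
    rdir <- cos(reg$phi0) * reg$e1 + sin(reg$phi0) * reg$e2
    centroid <- prim$a + u * (reg$s0 + reg$len / 2) +
      rdir * r * sin(alpha) / alpha
    list(area = reg$len * reg$w, centroid = centroid)
  }
}

#' Generate a paint patch on a synthetic bone
#'
#' The painted region is defined analytically on one host primitive: a
#' spherical cap, a star-shaped ("polygonal") geodesic region on a sphere, or
#' a linear strip on a cylindrical shaft.  The patch mesh is a thin shell of
#' the covered bone faces offset outward along the primitive normal; ground
#' truth area and centroid come from closed forms (cap, strip) or azimuthal
#' quadrature (polygonal).
#'
#' @param bone a `SyntheticBone`.
#' @param shape_class `"cap"`, `"polygonal"` or `"linear"`.
#' @param location_params named list.  cap/polygonal: `primitive` (name of a
#'   sphere primitive), `axis` (outward direction), `theta` (half-angle,
#'   radians), polygonal also `amp`, `k`, `phi_off`; linear: `primitive`
#'   (capsule name), `s0` (axial start, mm), `len`, `width` (arc width, mm),
#'   `phi0` (azimuth, radians).
#' @param seed integer, reserved for stochastic shape detail.
#' @param thickness outward shell offset in mm (<= 0.3).
#' @param name attachment name.
#' @param role `"origin"` or `"insertion"`.
#' @return an object of class `PaintPatch` with fields `mesh`, `host_bone`,
#'   `shape_class`, `truth_area` (mm^2), `truth_centroid` (mm), `region`.
#' @export
make_paint_patch <- function(bone, shape_class = c("cap", "polygonal", "linear"),
                             location_params = list(), seed = 1L,
                             thickness = 0.15, name = "patch",
                             role = c("origin", "insertion")) {
  shape_class <- match.arg(shape_class)
  role <- match.arg(role)
  if (thickness <= 0 || thickness > 0.3)
    stop("thickness must be in (0, 0.3] mm")
  lp <- location_params
  prim_name <- if (!is.null(lp$primitive)) lp$primitive else
    if (shape_class == "linear") "shaft" else "head"
  prim <- bone$primitives[[prim_name]]
  if (is.null(prim)) stop("no primitive named '", prim_name, "' on this bone")
  if (shape_class %in% c("cap", "polygonal")) {
    if (prim$type != "sphere") stop("cap/polygonal patches need a sphere host")
    theta <- if (!is.null(lp$theta)) lp$theta else pi / 7
    if (theta <= 0) stop("patch half-angle must be positive")
    if (theta > pi / 2) stop("cap patches must not exceed a hemisphere")
    axis <- normalize(if (!is.null(lp$axis)) lp$axis else c(0, 1, 0))
    fr <- .perp_frame(axis)
    reg <- list(axis = axis, theta = theta, e1 = fr$e1, e2 = fr$e2)
    if (shape_class == "polygonal") {
      reg$amp <- if (!is.null(lp$amp)) lp$amp else 0.25
      reg$k <- if (!is.null(lp$k)) lp$k else 5
      reg$phi_off <- if (!is.null(lp$phi_off)) lp$phi_off else 0
      if (reg$theta * (1 + reg$amp) > pi / 2)
        stop("polygonal patch must not exceed a hemisphere")
    }
  } else {
    if (prim$type != "capsule") stop("linear patches need a capsule host")
    L <- vnorm(prim$b - prim$a)
    len <- if (!is.null(lp$len)) lp$len else 60
    w <- if (!is.null(lp$width)) lp$width else 8
    if (len <= 0 || w <= 0) stop("strip length and width must be positive")
    if (len / w < 4) stop("linear strips require aspect ratio >= 4")
    if (w >= pi * prim$radius) stop("strip wider than half the shaft girth")
    s0 <- if (!is.null(lp$s0)) lp$s0 else (L - len) / 2
    if (s0 < 0 || s0 + len > L) stop("strip does not fit on the shaft")
    fr <- .perp_frame(normalize(prim$b - prim$a))
    reg <- list(s0 = s0, len = len, w = w,
                phi0 = if (!is.null(lp$phi0)) lp$phi0 else 0,
                e1 = fr$e1, e2 = fr$e2)
  }
  patch <- list(shape_class = shape_class, prim = prim, region = reg,
                host_bone = bone$kind, host_primitive = prim_name,
                thickness = thickness, name = name, role = role,
                seed = as.integer(seed))
  # shell mesh: covered bone faces, offset outward along the primitive normal
  sm <- NULL
  if (!is.null(bone$mesh)) {
    fc <- face_centroids(bone$mesh)
    sel <- which(patch_membership(patch, fc, surf_tol = 0.75 * bone$pitch + 0.05))
    if (!length(sel)) stop("patch region covers no bone surface")
    sm <- submesh(bone$mesh, sel)
    nrm <- if (prim$type == "sphere") {
      rel <- sweep(sm$vertices, 2, prim$center)
      rel / pmax(sqrt(rowSums(rel^2)), 1e-9)
    } else {
      sg <- .seg_geom(sm$vertices, prim$a, prim$b)
      ax <- outer(pmin(pmax(sg$t, 0), sg$len), sg$u)
      rad <- sweep(sm$vertices, 2, prim$a) - ax
      rad / pmax(sqrt(rowSums(rad^2)), 1e-9)
    }
    sm$vertices <- sm$vertices + thickness * nrm
  }
  tr <- .patch_truth(shape_class, prim, reg)
  patch$mesh <- sm
  patch$truth_area <- tr$area
  patch$truth_centroid <- as.numeric(tr$centroid)
  structure(patch, class = "PaintPatch")
}

#' @export
print.PaintPatch <- function(x, ...) {
  cat(sprintf("PaintPatch '%s' (%s, %s on %s): truth area %.1f mm^2\n",
              x$name, x$role, x$shape_class, x$host_bone, x$truth_area))
  invisible(x)
}

# --- scenes -----------------------------------------------------------------

#' Assemble a synthetic specimen scene
#'
#' A scene bundles named bones, paint patches and specimen landmarks.  The
#' default scene is a right-convention femur carrying five knee-related
#' attachment marks (condylar caps for the gastrocnemius heads, shaft strips
#' for vastus lateralis and the short biceps head, and a polygonal mark on
#' the head).
#'
#' @param params list: `bones` (character vector of kinds), `femur` size
#'   overrides, `patches` (list of patch specs: `name`, `shape`, `params`,
#'   `role`), `pitch`.
#' @param seed integer RNG seed.
#' @return an object of class `SyntheticScene`.
#' @export
make_synthetic_scene <- function(params = list(), seed = 1L) {
  pitch <- if (!is.null(params$pitch)) params$pitch else 0.8
  do_mesh <- params$mesh %||% TRUE
  kinds <- if (!is.null(params$bones)) params$bones else "femur"
  bones <- list()
  for (k in kinds) {
    bones[[k]] <- make_synthetic_bone(k, size_params = params[[k]] %||% list(),
                                      seed = seed, pitch = pitch,
                                      mesh = do_mesh)
  }
  femur <- bones[["femur"]]
  specs <- params$patches %||% default_patch_set()
  patches <- list()
  if (!is.null(femur)) {
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      patches[[sp$name]] <- make_paint_patch(
        femur, shape_class = sp$shape, location_params = sp$params,
        seed = seed + i, name = sp$name, role = sp$role %||% "origin")
    }
  }
  lms <- list()
  for (k in names(bones)) for (nm in names(bones[[k]]$landmarks))
    lms[[nm]] <- bones[[k]]$landmarks[[nm]]
  structure(list(bones = bones, patches = patches, landmarks = lms,
                 side = "right", rng_seed = as.integer(seed)),
            class = "SyntheticScene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname make_synthetic_scene
#' @export
default_patch_set <- function() {
  list(
    list(name = "gastrocnemius_caput_mediale_O", shape = "cap",
         params = list(primitive = "condyle_med",
                       axis = normalize(c(-0.5, -0.45, -0.74)), theta = 0.50)),
    list(name = "gastrocnemius_caput_laterale_O", shape = "cap",
         params = list(primitive = "condyle_lat",
                       axis = normalize(c(-0.5, -0.45, 0.74)), theta = 0.55)),
    list(name = "vastus_lateralis_O", shape = "linear",
         params = list(primitive = "shaft", len = 120, width = 14,
                       phi0 = 2.0, s0 = 120)),
    list(name = "biceps_femoris_caput_breve_O", shape = "linear",
         params = list(primitive = "shaft", len = 100, width = 8,
                       phi0 = pi, s0 = 40)),
    list(name = "piriformis_fossa_O", shape = "polygonal",
         params = list(primitive = "head", axis = c(0, 1, 0), theta = 0.35,
                       amp = 0.25, k = 5)))
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf("SyntheticScene (%s side, seed %d): bones [%s], %d patches\n",
              x$side, x$rng_seed, paste(names(x$bones), collapse = ", "),
              length(x$patches)))
  invisible(x)
}

#' Mirror a scene about the sagittal plane (z -> -z)
#'
#' Used to express left-sided specimens; landmark labels keep their
#' anatomical meaning (the lateral epicondyle stays lateral).
#'
#' @param scene a `SyntheticScene`.
#' @return the mirrored scene, with `side` flipped.
#' @export
mirror_scene <- function(scene) {
  for (k in names(scene$bones)) {
    b <- scene$bones[[k]]
    if (!is.null(b$mesh)) b$mesh <- mirror_mesh(b$mesh)
    b$primitives <- lapply(b$primitives, prim_mirror)
    b$landmarks <- lapply(b$landmarks, .mirror_vec)
    b$side <- if (b$side == "right") "left" else "right"
    scene$bones[[k]] <- b
  }
  for (nm in names(scene$patches)) {
    pa <- scene$patches[[nm]]
    pa$prim <- prim_mirror(pa$prim)
    # the region's own frame mirrors with the geometry, so angular
    # parameters (theta, phi0, phi_off) stay valid verbatim
    for (fld in c("axis", "e1", "e2"))
      if (!is.null(pa$region[[fld]]))
        pa$region[[fld]] <- .mirror_vec(pa$region[[fld]])
    if (!is.null(pa$mesh)) pa$mesh <- mirror_mesh(pa$mesh)
    pa$truth_centroid <- .mirror_vec(pa$truth_centroid)
    scene$patches[[nm]] <- pa
  }
  scene$landmarks <- lapply(scene$landmarks, .mirror_vec)
  scene$side <- if (scene$side == "right") "left" else "right"
  scene
}

#' Apply a small rigid perturbation to a scene
#'
#' Emulates inter-scan repositioning: a random rotation (degrees SD per axis)
#' and translation (mm SD) applied to every bone, patch and landmark.
#'
#' @param scene a `SyntheticScene`.
#' @param angle_sd rotation SD per Euler axis, degrees.
#' @param trans_sd translation SD per axis, mm.
#' @param seed integer seed.
#' @return the perturbed scene; the applied transform is stored in
#'   `$perturbation` (list `rotation`, `translation`).
#' @export
perturb_scene <- function(scene, angle_sd = 1, trans_sd = 2, seed = 1L) {
  par <- with_seed(seed, list(ang = rnorm(3, 0, angle_sd) * pi / 180,
                              tr = rnorm(3, 0, trans_sd)))
  R <- euler_rotation(par$ang[1], par$ang[2], par$ang[3])
  tr <- par$tr
  rot_vec <- function(v) as.numeric(R %*% v)
  map_pt <- function(v) as.numeric(R %*% v + tr)
  for (k in names(scene$bones)) {
    b <- scene$bones[[k]]
    b$mesh <- transform_mesh(b$mesh, R, tr)
    b$primitives <- lapply(b$primitives, function(pr) {
      if (pr$type == "sphere") pr$center <- map_pt(pr$center)
      else { pr$a <- map_pt(pr$a); pr$b <- map_pt(pr$b) }
      pr
    })
    b$landmarks <- lapply(b$landmarks, map_pt)
    scene$bones[[k]] <- b
  }
  for (nm in names(scene$patches)) {
    pa <- scene$patches[[nm]]
    if (pa$prim$type == "sphere") pa$prim$center <- map_pt(pa$prim$center)
    else { pa$prim$a <- map_pt(pa$prim$a); pa$prim$b <- map_pt(pa$prim$b) }
    for (fld in c("axis", "e1", "e2"))
      if (!is.null(pa$region[[fld]]))
        pa$region[[fld]] <- rot_vec(pa$region[[fld]])
    if (!is.null(pa$mesh)) pa$mesh <- transform_mesh(pa$mesh, R, tr)
    pa$truth_centroid <- map_pt(pa$truth_centroid)
    scene$patches[[nm]] <- pa
  }
  scene$landmarks <- lapply(scene$landmarks, map_pt)
  scene$perturbation <- list(rotation = R, translation = tr)
  scene
}

# intrinsic XYZ Euler rotation
euler_rotation <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# --- voxelization -----------------------------------------------------------

#' Default Hounsfield-unit assignments
#'
#' Cortical bone and paint both exceed the 250 HU bone-window minimum; the
#' paint value is separable from bone by a secondary threshold at 2000 HU.
#' @export
default_hu_map <- function() {
  c(air = -1000, soft_tissue = 40, cortical_bone = 1200, paint = 2600)
}

#' Voxelize a scene into a CT-like volume
#'
#' Voxel centres inside any bone receive the bone HU; centres within a paint
#' shell (within `max(thickness, 0.55 * spacing)` of a painted region of the
#' host surface, emulating paint/bone interblending at finite resolution)
#' receive the paint HU; centres within 12 mm of a bone receive soft-tissue
#' HU; everything else is air.  Optional additive Gaussian noise.
#'
#' @param scene a `SyntheticScene`.
#' @param spacing voxel spacing, scalar or length-3 (mm).
#' @param hu_map named HU values for `air`, `soft_tissue`, `cortical_bone`,
#'   `paint`.
#' @param noise_sd additive Gaussian noise SD (HU).
#' @param seed integer seed for the noise stream.
#' @return an object of class `CTVolume`: `values` (3D array, HU), `spacing`,
#'   `origin` (mm, centre of voxel `[1,1,1]`).  Patches spanning fewer than
#'   two voxels are recorded in `attr(, "warnings")`.
#' @export
voxelize_scene <- function(scene, spacing = 1.0, hu_map = default_hu_map(),
                           noise_sd = 0, seed = 1L) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  sp <- rep(as.numeric(spacing), length.out = 3)
  need <- c("air", "soft_tissue", "cortical_bone", "paint")
  if (!all(need %in% names(hu_map)))
    stop("hu_map must name: ", paste(need, collapse = ", "))
  all_prims <- unlist(lapply(scene$bones, `[[`, "primitives"),
                      recursive = FALSE, use.names = FALSE)
  if (!length(all_prims)) {
    dims <- c(8L, 8L, 8L)
    vals <- array(hu_map[["air"]], dims)
    if (noise_sd > 0)
      vals <- vals + with_seed(seed, array(rnorm(length(vals), 0, noise_sd), dims))
    return(structure(list(values = vals, spacing = sp, origin = c(0, 0, 0)),
                     class = "CTVolume"))
  }
  bb <- prims_bbox(all_prims, margin = 14)
  dims <- pmax(ceiling((bb$hi - bb$lo) / sp) + 1L, 2L)
  gx <- bb$lo[1] + (seq_len(dims[1]) - 1) * sp[1]
  gy <- bb$lo[2] + (seq_len(dims[2]) - 1) * sp[2]
  gz <- bb$lo[3] + (seq_len(dims[3]) - 1) * sp[3]
  vals <- array(hu_map[["air"]], dims)
  shell_w <- function(pa) max(pa$thickness, 0.55 * max(sp))
  n_paint <- setNames(numeric(length(scene$patches)), names(scene$patches))
  xy <- cbind(rep(gx, times = dims[2]), rep(gy, each = dims[1]))
  for (k in seq_len(dims[3])) {
    P <- cbind(xy, gz[k])
    slab <- rep(hu_map[["air"]], nrow(P))
    soft <- prims_inside(all_prims, P, inflate = 12)
    slab[soft] <- hu_map[["soft_tissue"]]
    bone <- prims_inside(all_prims, P)
    slab[bone] <- hu_map[["cortical_bone"]]
    for (nm in names(scene$patches)) {
      pa <- scene$patches[[nm]]
      pm <- patch_membership(pa, P, surf_tol = shell_w(pa))
      n_paint[nm] <- n_paint[nm] + sum(pm)
      slab[pm] <- hu_map[["paint"]]
    }
    vals[, , k] <- slab
  }
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, array(rnorm(length(vals), 0, noise_sd), dims))
  out <- structure(list(values = vals, spacing = sp, origin = bb$lo),
                   class = "CTVolume")
  coarse <- names(n_paint)[n_paint < 2]
  if (length(coarse))
    attr(out, "warnings") <- paste0("patch '", coarse,
                                    "' spans fewer than 2 voxels at this spacing")
  out
}

#' @export
print.CTVolume <- function(x, ...) {
  cat(sprintf("CTVolume: %s voxels at (%.2f, %.2f, %.2f) mm; HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# --- cohorts ----------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws `n_specimens` scenes around a base scene.  Patch areas vary
#' log-normally around the base area with the requested coefficient of
#' variation (multiplicative factors with mean 1); patch locations receive
#' surface jitter; bone dimensions vary log-normally with their own CV.
#' Defaults mirror the study conditions: four specimens (three left, one
#' right), attachment-area CV 33%, femoral-dimension CV 7%.
#'
#' @param n_specimens number of specimens (>= 2).
#' @param base_scene_params passed to [make_synthetic_scene()].
#' @param variation_params list: `area_cv` (percent), `jitter_sd` (mm),
#'   `bone_cv` (percent).
#' @param seed integer seed.
#' @param mesh when `FALSE`, scenes carry only implicit models and analytic
#'   truth (fast; used for statistical calibration at large `n_specimens`).
#' @return list with `scenes` (list of `SyntheticScene`) and `truth` (a
#'   `GroundTruth` object: data frames `patches` and `bones`).
#' @export
make_cohort <- function(n_specimens = 4, base_scene_params = list(),
                        variation_params = list(), seed = 1L, mesh = TRUE) {
  if (n_specimens < 2) stop("a cohort needs at least 2 specimens")
  vp <- variation_params
  area_cv <- (vp$area_cv %||% 33) / 100
  jitter_sd <- vp$jitter_sd %||% 2
  bone_cv <- (vp$bone_cv %||% 7) / 100
  if (area_cv < 0 || bone_cv < 0) stop("CV values must be non-negative")
  if (jitter_sd < 0) stop("jitter SD must be non-negative")
  sides <- rep("left", n_specimens)
  sides[n_specimens] <- "right"

  rln <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    exp(rnorm(n, -s2 / 2, sqrt(s2)))
  }
  base <- base_scene_params
  patch_specs <- base$patches %||% default_patch_set()
  np <- length(patch_specs)
  draws <- with_seed(seed, list(
    area = matrix(rln(n_specimens * np, area_cv), n_specimens, np),
    bone = matrix(rln(n_specimens * 4, bone_cv), n_specimens, 4),
    jit_ang = matrix(rnorm(n_specimens * np, 0, 1), n_specimens, np),
    jit_ax = matrix(rnorm(n_specimens * np, 0, 1), n_specimens, np)))

  fem0 <- base$femur %||% list()
  g0 <- function(nm, def) fem0[[nm]] %||% def
  scenes <- vector("list", n_specimens)
  pat_rows <- list(); bone_rows <- list()
  for (i in seq_len(n_specimens)) {
    fem <- list(length = g0("length", 405.38) * draws$bone[i, 1],
                tea = g0("tea", 91.65) * draws$bone[i, 2],
                head_radius = g0("head_radius", 25.465) * draws$bone[i, 3],
                shaft_radius = g0("shaft_radius", 17.85) * draws$bone[i, 4])
    specs_i <- patch_specs
    for (j in seq_len(np)) {
      sc <- sqrt(draws$area[i, j])  # linear scale from the area factor
      pp <- specs_i[[j]]$params
      if (specs_i[[j]]$shape %in% c("cap", "polygonal")) {
        host_r <- if (identical(pp$primitive %||% "head", "head"))
          fem$head_radius else g0("condyle_radius", 21)
        pp$theta <- min((pp$theta %||% (pi / 7)) * sc, pi / 2 * 0.98)
        ang_j <- jitter_sd / host_r
        pp$axis <- normalize((pp$axis %||% c(0, 1, 0)) +
                               ang_j * c(draws$jit_ang[i, j], 0, draws$jit_ax[i, j]))
      } else {
        pp$len <- (pp$len %||% 60) * sc
        # painted strips narrower than ~5 mm are below the method's
        # resolving scale; keep the realized width physical
        pp$width <- max(5, (pp$width %||% 8) * sc)
        pp$s0 <- max(0, (pp$s0 %||% 60) + jitter_sd * draws$jit_ax[i, j])
        pp$phi0 <- (pp$phi0 %||% 0) +
          jitter_sd * draws$jit_ang[i, j] / fem$shaft_radius
      }
      specs_i[[j]]$params <- pp
    }
    params_i <- base
    params_i$femur <- utils::modifyList(fem0, fem)
    params_i$patches <- specs_i
    params_i$mesh <- mesh
    # one shared shape seed: all inter-specimen variation comes from the
    # explicit draws, so a requested CV of zero yields identical specimens
    sc_i <- make_synthetic_scene(params_i, seed = seed)
    if (sides[i] == "left") sc_i <- mirror_scene(sc_i)
    sc_i$specimen <- i
    scenes[[i]] <- sc_i
    for (nm in names(sc_i$patches)) {
      pa <- sc_i$patches[[nm]]
      pat_rows[[length(pat_rows) + 1L]] <- data.frame(
        specimen = i, name = nm, shape = pa$shape_class,
        truth_area = pa$truth_area,
        cx = pa$truth_centroid[1], cy = pa$truth_centroid[2],
        cz = pa$truth_centroid[3], side = sides[i])
    }
    bone_rows[[length(bone_rows) + 1L]] <- data.frame(
      specimen = i, side = sides[i], ma = fem$length, tea = fem$tea,
      fhd = 2 * fem$head_radius, sd = 2 * fem$shaft_radius)
  }
  truth <- structure(list(patches = do.call(rbind, pat_rows),
                          bones = do.call(rbind, bone_rows),
                          area_cv_requested = area_cv * 100,
                          jitter_sd = jitter_sd, seed = as.integer(seed),
                          perturbations = list()),
                     class = "GroundTruth")
  list(scenes = scenes, truth = truth)
}

#' Serialize ground truth to JSON and back
#'
#' @param truth a `GroundTruth` object.
#' @param path file path.
#' @return `read_ground_truth` returns the `GroundTruth`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$patches <- as.data.frame(x$patches)
  x$bones <- as.data.frame(x$bones)
  structure(x, class = "GroundTruth")
}
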