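test_that("a cap footprint is recovered to its analytic area", {
  b <- fixture("femur_head25", function()
    make_synthetic_bone("femur", list(head_radius = 25), seed = 2))
  pa <- make_paint_patch(b, "cap",
                         list(primitive = "head", axis = c(0, 1, 0),
                              theta = pi / 6))
  fp <- trace_contact_area(b$mesh, pa$mesh, epsilon = 0.5)
  expect_lt(rel_err(fp$area, 2 * pi * 625 * (1 - cos(pi / 6))), 0.03)
  expect_lt(sqrt(sum((fp$centroid - pa$truth_centroid)^2)), 1)
  # paint lifted 10 mm radially off the bone finds nothing
  off <- pa$mesh
  off$vertices[, 2] <- off$vertices[, 2] + 10  # along the cap axis, outward
  expect_error(trace_contact_area(b$mesh, off, epsilon = 0.5),
               "no bone face")
})

test_that("full paint coverage recovers the whole sphere area", {
  sph <- fixture("gen_sphere", function()
    make_synthetic_bone("generic", list(radius = 20), seed = 4, pitch = 0.8))
  shell <- sph$mesh
  shell$vertices <- shell$vertices * (1 + 0.15 / 20)  # uniform 0.15 mm offset
  fp <- trace_contact_area(sph$mesh, shell, epsilon = 0.5)
  expect_lt(rel_err(fp$area, 4 * pi * 400), 0.03)
})

test_that("footprint centroid matches simple and sampled oracles", {
  g <- grid_mesh(10, 10)
  expect_equal(footprint_centroid(g), c(0.5, 0.5, 0), tolerance = 1e-12)
  # symmetric parametric cap: centroid laterally on the axis
  cap <- sphere_band_mesh(r = 25, psi1 = pi / 6)
  ctr <- footprint_centroid(cap)
  expect_lt(max(abs(ctr[c(1, 3)])), 1e-6)
  # irregular patch vs dense uniform-sampling Monte-Carlo centroid
  b <- fixture_femur()
  pa <- make_paint_patch(b, "polygonal",
                         list(primitive = "head", axis = c(0, 1, 0),
                              theta = 0.35))
  fp <- trace_contact_area(b$mesh, pa$mesh)
  set.seed(55)
  smp <- sample_surface(fp$submesh, 200000)
  expect_lt(sqrt(sum((colMeans(smp) - fp$centroid)^2)), 0.5)
})

test_that("best-fit planes behave on planar, curved and degenerate input", {
  g <- grid_mesh(8, 8)
  pl <- best_fit_plane(g)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_lt(max(abs(g$vertices %*% pl$normal -
                      sum(pl$point * pl$normal))), 1e-9)
  cap <- sphere_band_mesh(r = 25, psi1 = pi / 6)
  pc <- best_fit_plane(cap)
  ang <- acos(abs(sum(pc$normal * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 1)
  # outward orientation: away from the sphere centre
  expect_gt(sum(pc$normal * c(0, 1, 0)), 0)
  line <- triangle_mesh(cbind(0:5, 0, 0), cbind(1:4, 2:5, 3:6))
  expect_error(best_fit_plane(line), "collinear|zero")
})

test_that("breakthrough points lie on the surface, with fallback for holes", {
  g <- grid_mesh(10, 10)
  bt <- breakthrough_point(g)
  expect_equal(as.numeric(bt), c(0.5, 0.5, 0), tolerance = 1e-9)
  expect_false(attr(bt, "fallback"))

  cap <- sphere_band_mesh(r = 25, psi1 = pi / 6)
  btc <- breakthrough_point(cap)
  expect_lt(sqrt(sum((as.numeric(btc) - c(0, 25, 0))^2)), 0.2)

  ring <- sphere_band_mesh(r = 25, psi0 = 20 * pi / 180,
                           psi1 = 40 * pi / 180)
  btr <- breakthrough_point(ring)
  expect_true(attr(btr, "fallback"))
  # fallback equals the brute-force nearest surface point to the centroid
  ctr <- footprint_centroid(ring)
  d_bt <- sqrt(sum((as.numeric(btr) - ctr)^2))
  expect_equal(d_bt, brute_closest_dist(matrix(ctr, 1, 3), ring)[1],
               tolerance = 1e-9)
  # on the inner rim: polar angle near the inner boundary
  psi_bt <- acos(btr[2] / 25)
  expect_lt(abs(psi_bt - 20 * pi / 180), 0.06)
})

test_that("linear thirds split a uniform strip into equal parts", {
  strip <- grid_mesh(60, 8, lx = 60, ly = 8)
  fp <- footprint(strip, seq_len(nrow(strip$faces)), name = "strip")
  parts <- subdivide(fp, subdivision_spec("linear_thirds",
                                          axis = c(1, 0, 0)))
  expect_identical(length(parts), 3L)
  for (p in parts) expect_lt(rel_err(p$area, fp$area / 3), 0.02)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "area")), fp$area,
               tolerance = 1e-12)
})

test_that("subdivision children partition the parent exactly", {
  b <- fixture_femur()
  pa <- make_paint_patch(b, "linear", list(len = 60, width = 8))
  fp <- trace_contact_area(b$mesh, pa$mesh)
  for (rule in c("linear_thirds", "thinnest_part")) {
    parts <- subdivide(fp, subdivision_spec(rule, axis = c(0, 1, 0)))
    got <- sort(unlist(lapply(parts, function(p) p$face_ids)))
    expect_identical(got, seq_len(nrow(fp$submesh$faces)))
    expect_equal(sum(vapply(parts, `[[`, numeric(1), "area")), fp$area,
                 tolerance = 1e-9)
    for (p in parts) {
      d <- closest_on_mesh(matrix(p$breakthrough_point, 1, 3), p$submesh)
      expect_lt(d$distance, 1e-6)
    }
  }
})

test_that("the 2x3 rule yields exactly six non-empty parts on a wrap patch", {
  b <- fixture_femur()
  pa <- make_paint_patch(b, "linear", list(len = 120, width = 24, s0 = 100),
                         name = "vi_like")
  fp <- trace_contact_area(b$mesh, pa$mesh)
  parts <- subdivide(fp, subdivision_spec("vastus_intermedius_2x3",
                                          axis = c(0, 1, 0)))
  expect_identical(length(parts), 6L)
  expect_true(all(vapply(parts, `[[`, numeric(1), "area") > 0))
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "area")), fp$area,
               tolerance = 1e-9)
})

test_that("plane splits honour the given plane and fail when it misses", {
  strip <- grid_mesh(20, 6, lx = 20, ly = 6)
  fp <- footprint(strip, seq_len(nrow(strip$faces)))
  spec <- subdivision_spec("plane_split",
                           plane_points = rbind(c(10, 0, 0), c(10, 6, 0),
                                                c(10, 3, 5)))
  parts <- subdivide(fp, spec)
  expect_identical(length(parts), 2L)
  expect_lt(rel_err(parts[[1]]$area, fp$area / 2), 0.02)
  miss <- subdivision_spec("plane_split",
                           plane_points = rbind(c(100, 0, 0), c(100, 6, 0),
                                                c(100, 3, 5)))
  expect_error(subdivide(fp, miss), "empty part")
})

test_that("the thinnest-part rule cuts a bowtie at its waist", {
  g <- grid_mesh(40, 10, lx = 40, ly = 10)
  fc <- face_centroids(g)
  # bowtie: drop faces near the middle except a narrow neck
  keep <- !(abs(fc[, 1] - 20) < 6 & abs(fc[, 2] - 5) > 1.5)
  fp <- footprint(g, which(keep), name = "bowtie")
  parts <- subdivide(fp, subdivision_spec("thinnest_part", axis = c(1, 0, 0)))
  expect_identical(length(parts), 2L)
  # both halves carry roughly half the area
  ar <- vapply(parts, `[[`, numeric(1), "area")
  expect_lt(abs(ar[1] - ar[2]) / sum(ar), 0.2)
})

test_that("trace area grows monotonically with epsilon", {
  b <- fixture("femur_head25", function()
    make_synthetic_bone("femur", list(head_radius = 25), seed = 2))
  pa <- make_paint_patch(b, "cap",
                         list(primitive = "head", axis = c(0, 1, 0),
                              theta = pi / 6))
  areas <- vapply(c(0.3, 0.5, 1.0, 2.0), function(eps)
    trace_contact_area(b$mesh, pa$mesh, epsilon = eps)$area, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("footprint quantities are equivariant under joint rigid motion", {
  b <- fixture("femur_head25", function()
    make_synthetic_bone("femur", list(head_radius = 25), seed = 2))
  pa <- make_paint_patch(b, "cap",
                         list(primitive = "head", axis = c(0, 1, 0),
                              theta = pi / 6))
  fp0 <- trace_contact_area(b$mesh, pa$mesh)
  R <- ctfootprint:::euler_rotation(0.3, 0.7, -0.4)
  tr <- c(11, -6, 23)
  fp1 <- trace_contact_area(transform_mesh(b$mesh, R, tr),
                            transform_mesh(pa$mesh, R, tr))
  expect_equal(fp1$area, fp0$area, tolerance = 1e-9)
  expect_equal(fp1$centroid, as.numeric(R %*% fp0$centroid + tr),
               tolerance = 1e-6)
  expect_equal(fp1$breakthrough_point,
               as.numeric(R %*% fp0$breakthrough_point + tr),
               tolerance = 1e-6)
})

test_that("overlapping marks resolve to the nearer paint deterministically", {
  b <- fixture("femur_head25", function()
    make_synthetic_bone("femur", list(head_radius = 25), seed = 2))
  p1 <- make_paint_patch(b, "cap", list(primitive = "head",
                                        axis = c(0, 1, 0), theta = 0.45),
                         name = "alpha")
  p2 <- make_paint_patch(b, "cap",
                         list(primitive = "head",
                              axis = c(0.55, 1, 0) / sqrt(1.3025),
                              theta = 0.45),
                         name = "beta")
  fps <- trace_footprints(b$mesh, list(beta = p2$mesh, alpha = p1$mesh))
  expect_setequal(names(fps), c("alpha", "beta"))
  # contested faces go to exactly one owner
  expect_identical(length(intersect(fps$alpha$face_ids, fps$beta$face_ids)),
                   0L)
  tot <- fps$alpha$area + fps$beta$area
  expect_lt(tot, p1$truth_area + p2$truth_area)  # overlap counted once
})
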