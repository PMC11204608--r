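test_that("bone generation is deterministic and validates parameters", {
  b1 <- make_synthetic_bone("femur", seed = 7, pitch = 1.6)
  b2 <- make_synthetic_bone("femur", seed = 7, pitch = 1.6)
  expect_identical(b1$mesh$vertices, b2$mesh$vertices)
  expect_identical(b1$mesh$faces, b2$mesh$faces)
  expect_error(make_synthetic_bone("femur", list(head_radius = -1)),
               "positive")
})

test_that("femur landmarks are consistent with the constructed head", {
  b <- fixture_femur()
  expect_true(is_watertight(b$mesh))
  fm <- measure_femur(b$mesh, b$landmarks)
  # sphere_fit recovers the head-centre landmark from the mesh
  expect_lt(sqrt(sum((fm$head_center - b$landmarks$head_center)^2)), 0.1)
  expect_equal(fm$TEA, 91.65, tolerance = 1e-9)
})

test_that("femur mesh volume matches a voxel-counting oracle", {
  b <- make_synthetic_bone("femur",
                           list(length = 400, head_radius = 25),
                           seed = 3, pitch = 1.2)
  prims <- b$primitives
  bb <- ctfootprint:::prims_bbox(prims, margin = 1)
  h <- 0.5
  gx <- seq(bb$lo[1], bb$hi[1], by = h)
  gy <- seq(bb$lo[2], bb$hi[2], by = h)
  gz <- seq(bb$lo[3], bb$hi[3], by = h)
  n_in <- 0
  xy <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  for (z in gz)
    n_in <- n_in + sum(ctfootprint:::prims_inside(prims, cbind(xy, z)))
  oracle_vol <- n_in * h^3
  expect_lt(rel_err(mesh_volume(b$mesh), oracle_vol), 0.02)
})

test_that("cap patch truth follows the analytic cap formula", {
  b <- fixture("femur_head25", function()
    make_synthetic_bone("femur", list(head_radius = 25), seed = 2))
  pa <- make_paint_patch(b, "cap",
                         list(primitive = "head", axis = c(0, 1, 0),
                              theta = pi / 6))
  expect_equal(pa$truth_area, 2 * pi * 25^2 * (1 - cos(pi / 6)),
               tolerance = 1e-12)
  # centroid on the cap axis at r (1 + cos theta) / 2 above the centre
  expect_equal(pa$truth_centroid,
               b$landmarks$head_center + c(0, 25 * (1 + cos(pi / 6)) / 2, 0),
               tolerance = 1e-9)
  expect_error(make_paint_patch(b, "cap", list(theta = 0)), "positive")
  expect_error(make_paint_patch(b, "cap", list(theta = 2)), "hemisphere")
})

test_that("strip patch truth matches a surface-sampling oracle", {
  b <- fixture_femur()
  pa <- make_paint_patch(b, "linear", list(len = 60, width = 8))
  expect_equal(pa$truth_area, 480, tolerance = 1e-12)
  # Monte-Carlo oracle: uniform samples on the host cylinder surface
  prim <- pa$prim
  set.seed(99)
  n <- 4e5
  L <- sqrt(sum((prim$b - prim$a)^2))
  u <- (prim$b - prim$a) / L
  fr <- ctfootprint:::.perp_frame(u)
  t <- runif(n, 0, L)
  phi <- runif(n, -pi, pi)
  P <- matrix(prim$a, n, 3, byrow = TRUE) + outer(t, u) +
    prim$radius * (outer(cos(phi), fr$e1) + outer(sin(phi), fr$e2))
  frac <- mean(ctfootprint:::patch_membership(pa, P))
  mc_area <- frac * 2 * pi * prim$radius * L
  expect_lt(rel_err(pa$truth_area, mc_area), 0.01)
  expect_error(make_paint_patch(b, "linear", list(len = 10, width = 8)),
               "aspect")
})

test_that("polygonal patch truth agrees with a Monte-Carlo sphere oracle", {
  b <- fixture_femur()
  pa <- make_paint_patch(b, "polygonal",
                         list(primitive = "head", axis = c(0, 1, 0),
                              theta = 0.35))
  prim <- pa$prim
  set.seed(123)
  n <- 4e5
  z <- runif(n, -1, 1); az <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  P <- sweep(prim$radius * cbind(s * cos(az), z, s * sin(az)), 2,
             -prim$center)
  frac <- mean(ctfootprint:::patch_membership(pa, P))
  mc_area <- frac * 4 * pi * prim$radius^2
  expect_lt(rel_err(pa$truth_area, mc_area), 0.02)
  ctr_mc <- colMeans(P[ctfootprint:::patch_membership(pa, P), ])
  expect_lt(sqrt(sum((ctr_mc - pa$truth_centroid)^2)), 0.5)
})

test_that("paint shells hug the host bone surface", {
  b <- fixture_femur()
  for (shape in c("cap", "linear")) {
    pa <- make_paint_patch(b, shape,
                           if (shape == "cap")
                             list(primitive = "condyle_lat",
                                  axis = c(-0.5, -0.45, 0.74), theta = 0.5)
                           else list(len = 60, width = 8))
    d <- closest_on_mesh(pa$mesh$vertices, b$mesh)$distance
    expect_lt(max(d), 0.5)
    expect_gt(pa$truth_area, 0)
  }
})

test_that("voxelized sphere reproduces the analytic volume above threshold", {
  sc <- make_synthetic_scene(list(bones = "generic",
                                  generic = list(radius = 20),
                                  patches = list()), seed = 4)
  vol <- voxelize_scene(sc, spacing = 1, noise_sd = 0)
  v_mask <- sum(vol$values >= 250) * prod(vol$spacing)
  expect_lt(rel_err(v_mask, 4 / 3 * pi * 20^3), 0.03)
})

test_that("voxelization handles empty scenes and is seed-deterministic", {
  empty <- structure(list(bones = list(), patches = list(),
                          landmarks = list(), side = "right", rng_seed = 1L),
                     class = "SyntheticScene")
  v0 <- voxelize_scene(empty, spacing = 2)
  expect_true(all(v0$values == -1000))

  sc <- make_synthetic_scene(list(bones = "patella", patches = list()),
                             seed = 5)
  v1 <- voxelize_scene(sc, spacing = 1.5, noise_sd = 50, seed = 11)
  v2 <- voxelize_scene(sc, spacing = 1.5, noise_sd = 50, seed = 11)
  expect_identical(v1$values, v2$values)
  v3 <- voxelize_scene(sc, spacing = 1.5, noise_sd = 50, seed = 12)
  expect_false(identical(v1$values, v3$values))
})

test_that("cohort areas follow the requested coefficient of variation", {
  # zero CV: identical truth areas across specimens
  co0 <- make_cohort(n_specimens = 3,
                     variation_params = list(area_cv = 0, jitter_sd = 0,
                                             bone_cv = 0),
                     seed = 5, mesh = FALSE)
  spread <- tapply(co0$truth$patches$truth_area, co0$truth$patches$name,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-9))

  # requested 33% CV converges at large n (truth-only cohort)
  co <- make_cohort(n_specimens = 200,
                    variation_params = list(area_cv = 33, jitter_sd = 0,
                                            bone_cv = 0),
                    seed = 6, mesh = FALSE)
  tp <- co$truth$patches
  cvs <- tapply(tp$truth_area, tp$name, function(x)
    100 * sqrt(mean((x - mean(x))^2)) / mean(x))
  expect_true(all(abs(cvs - 33) < 5))

  expect_error(make_cohort(variation_params = list(area_cv = -1)),
               "non-negative")
})

test_that("cohorts are deterministic and honour the side convention", {
  co1 <- make_cohort(n_specimens = 4, seed = 9, mesh = FALSE)
  co2 <- make_cohort(n_specimens = 4, seed = 9, mesh = FALSE)
  expect_identical(co1$truth$patches, co2$truth$patches)
  sides <- vapply(co1$scenes, `[[`, character(1), "side")
  expect_identical(sides, c("left", "left", "left", "right"))
})

test_that("mirroring a scene mirrors geometry but keeps truth consistent", {
  sc <- make_synthetic_scene(list(pitch = 1.6), seed = 3)
  ms <- mirror_scene(sc)
  expect_identical(ms$side, "left")
  pa <- sc$patches[[1]]; pm <- ms$patches[[1]]
  expect_equal(pm$truth_centroid, pa$truth_centroid * c(1, 1, -1),
               tolerance = 1e-12)
  expect_equal(pm$truth_area, pa$truth_area, tolerance = 1e-12)
  expect_equal(mesh_volume(ms$bones$femur$mesh),
               mesh_volume(sc$bones$femur$mesh), tolerance = 1e-9)
  # landmarks keep anatomical labels, coordinates mirror
  expect_equal(ms$landmarks$epicondyle_lateral,
               sc$landmarks$epicondyle_lateral * c(1, 1, -1))
})

test_that("ground truth serializes losslessly", {
  co <- make_cohort(n_specimens = 3, seed = 2, mesh = FALSE)
  path <- tempfile(fileext = ".json")
  write_ground_truth(co$truth, path)
  back <- read_ground_truth(path)
  expect_lt(max(abs(back$patches$truth_area - co$truth$patches$truth_area)),
            1e-9)
  expect_lt(max(abs(back$bones$ma - co$truth$bones$ma)), 1e-9)
})
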