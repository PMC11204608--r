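test_that("HU window thresholding is inclusive at both bounds", {
  vals <- array(c(-1000, 40, 249, 250, 1200, 3000, 3001, 0), dim = c(2, 2, 2))
  vol <- ct_volume(vals, spacing = 1)
  m <- threshold_segment(vol, 250, 3000)
  expect_identical(as.logical(m$values)[1:7],
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(threshold_segment(vol, 3000, 250), "below")
  air <- ct_volume(array(-1000, c(3, 3, 3)))
  expect_warning(m0 <- threshold_segment(air), "no voxels")
  expect_false(any(m0$values))
})

test_that("window monotonicity: a wider window never removes voxels", {
  set.seed(21)
  vol <- ct_volume(array(runif(6^3, -1000, 3500), c(6, 6, 6)))
  m1 <- threshold_segment(vol, 300, 2500)
  m2 <- threshold_segment(vol, 250, 3000)
  expect_true(all(m2$values[m1$values]))
})

test_that("masked sphere volume matches the analytic value", {
  sc <- make_synthetic_scene(list(bones = "generic",
                                  generic = list(radius = 20),
                                  patches = list()), seed = 8)
  vol <- voxelize_scene(sc, spacing = 1)
  m <- threshold_segment(vol)
  expect_lt(rel_err(mask_volume(m), 4 / 3 * pi * 8000), 0.03)
})

test_that("split_paint partitions the primary mask", {
  sc <- fixture("scene_cap", function() make_synthetic_scene(list(
    pitch = 1.4,
    patches = list(list(name = "cap1", shape = "cap",
                        params = list(primitive = "head", axis = c(0, 1, 0),
                                      theta = 0.4)))), seed = 5))
  vol <- fixture("vol_cap", function() voxelize_scene(sc, spacing = 1.5,
                                                      seed = 5))
  primary <- threshold_segment(vol)
  lab <- split_paint(vol, primary)
  expect_false(any(lab$bone$values & lab$paint$values))
  expect_identical(lab$bone$values | lab$paint$values, primary$values)
  expect_gt(sum(lab$paint$values), 0)

  # paint voxel count vs an independent shell voxelization of the region
  pa <- sc$patches[[1]]
  dims <- dim(vol$values)
  gx <- vol$origin[1] + (seq_len(dims[1]) - 1) * vol$spacing[1]
  gy <- vol$origin[2] + (seq_len(dims[2]) - 1) * vol$spacing[2]
  gz <- vol$origin[3] + (seq_len(dims[3]) - 1) * vol$spacing[3]
  P <- cbind(rep(gx, times = dims[2] * dims[3]),
             rep(rep(gy, each = dims[1]), times = dims[3]),
             rep(gz, each = dims[1] * dims[2]))
  shell_w <- max(pa$thickness, 0.55 * max(vol$spacing))
  n_shell <- sum(ctfootprint:::patch_membership(pa, P, surf_tol = shell_w))
  # the paint label adds a one-voxel interblending rim inside the bone, so
  # compare against the shell dilated into the mask (ratio bounded by the
  # 26-neighbourhood growth of a thin shell, checked loosely)
  expect_gt(sum(lab$paint$values), 0.9 * n_shell)
  expect_lt(sum(lab$paint$values), 4.0 * n_shell)

  # boundary cases
  lab2 <- split_paint(vol, primary, paint_hu_min = 4000)
  expect_false(any(lab2$paint$values))
  expect_identical(lab2$bone$values, primary$values)
  lab3 <- split_paint(vol, primary, paint_hu_min = 250)
  expect_false(any(lab3$bone$values))
})

test_that("extract_surface reproduces the analytic sphere area", {
  sc <- make_synthetic_scene(list(bones = "generic",
                                  generic = list(radius = 20),
                                  patches = list()), seed = 8)
  vol <- voxelize_scene(sc, spacing = 1)
  m <- threshold_segment(vol)
  mesh <- extract_surface(m)
  expect_true(is_watertight(mesh))
  expect_lt(rel_err(mesh_area(mesh), 4 * pi * 400), 0.03)
  # segmentation-meshing consistency
  expect_lt(rel_err(mesh_volume(mesh), mask_volume(m)), 0.05)
})

test_that("extract_surface handles single voxels and empty masks", {
  vals <- array(FALSE, c(5, 5, 5)); vals[3, 3, 3] <- TRUE
  mask <- structure(list(values = vals, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), label = "bone"),
                    class = "LabelMask")
  m <- extract_surface(mask, field_smoothing = 0L)
  expect_true(is_watertight(m))
  expect_true(is_consistently_oriented(m))
  # the 0.5-level midpoint polyhedron of one voxel encloses half the voxel
  # volume; its area lies between the octahedron and the voxel cube
  expect_equal(mesh_volume(m), 0.5, tolerance = 1e-9)
  expect_gt(mesh_area(m), sqrt(3))
  expect_lt(mesh_area(m), 6)

  mask$values[] <- FALSE
  expect_error(extract_surface(mask), "empty")
})

test_that("largest-component rule drops detached fragments", {
  vals <- array(FALSE, c(12, 6, 6))
  vals[2:5, 2:5, 2:5] <- TRUE     # big block
  vals[9, 3, 3] <- TRUE           # stray voxel
  mask <- structure(list(values = vals, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), label = "bone"),
                    class = "LabelMask")
  all_m <- extract_surface(mask, keep = "all", field_smoothing = 0L)
  big_m <- extract_surface(mask, keep = "largest_component",
                           field_smoothing = 0L)
  expect_identical(length(unique(mesh_components(all_m))), 2L)
  expect_identical(length(unique(mesh_components(big_m))), 1L)
  expect_lt(mesh_area(big_m), mesh_area(all_m))
})
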