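test_that("rigid transforms compose, invert and validate", {
  R1 <- ctfootprint:::euler_rotation(0.2, -0.4, 0.9)
  t1 <- c(3, -2, 7)
  tf <- rigid_transform(R1, t1)
  # compose with inverse is the identity
  id <- rt_compose(rt_invert(tf), tf)
  expect_lt(ctfootprint:::rt_angle_deg(id), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  # composition equals direct chaining on points
  tf2 <- rigid_transform(ctfootprint:::euler_rotation(-0.7, 0.1, 0.3),
                         c(-1, 5, 2))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(rt_apply(rt_compose(tf2, tf), p),
               rt_apply(tf2, rt_apply(tf, p)), tolerance = 1e-12)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "determinant")
})

test_that("alignment of a mesh with itself is the identity", {
  m <- fixture_femur_coarse()$mesh
  tf <- rigid_align(m, m)
  expect_lt(ctfootprint:::rt_angle_deg(tf), 1e-6)
  expect_lt(max(abs(tf$translation)), 1e-6)
})

test_that("ICP recovers a known 10 degree / 5 mm rigid motion", {
  b <- fixture_femur_coarse()
  R <- ctfootprint:::euler_rotation(0, 0, 10 * pi / 180)
  tr <- c(5, -3, 2)
  mov <- transform_mesh(b$mesh, R, tr)
  tf <- rigid_align(mov, b$mesh)
  resid <- rt_compose(tf, rigid_transform(R, tr))
  expect_lt(ctfootprint:::rt_angle_deg(resid), 0.05)
  expect_lt(sqrt(sum(rt_apply(resid, matrix(0, 1, 3))^2)), 0.05)
})

test_that("landmark initialization handles good and degenerate input", {
  b <- fixture_femur_coarse()
  R <- ctfootprint:::euler_rotation(0.1, 0.4, -0.3)
  tr <- c(40, -25, 60)  # too far for blind ICP, fine with landmarks
  mov <- transform_mesh(b$mesh, R, tr)
  lm_fix <- do.call(rbind, b$landmarks)
  lm_mov <- t(apply(lm_fix, 1, function(p) as.numeric(R %*% p + tr)))
  tf <- rigid_align(mov, b$mesh,
                    init_landmarks = list(moving = lm_mov, fixed = lm_fix))
  resid <- rt_compose(tf, rigid_transform(R, tr))
  expect_lt(ctfootprint:::rt_angle_deg(resid), 0.05)
  collin <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  expect_error(rigid_align(mov, b$mesh,
                           init_landmarks = list(moving = collin,
                                                 fixed = collin)),
               "collinear")
})

test_that("ICP tolerates vertex noise near its floor", {
  b <- fixture_femur_coarse()
  set.seed(31)
  noisy <- b$mesh
  noisy$vertices <- noisy$vertices + matrix(rnorm(length(noisy$vertices),
                                                  sd = 0.2),
                                            ncol = 3)
  tf <- rigid_align(noisy, b$mesh)
  expect_lt(attr(tf, "mean_distance"), 0.3)
})

test_that("deviation of identical and parallel surfaces is exact", {
  g <- grid_mesh(10, 10)
  set.seed(5)
  d0 <- deviation_analysis(g, g, 2000)
  expect_equal(d0$mean, 0, tolerance = 1e-12)
  expect_equal(d0$std, 0, tolerance = 1e-12)
  # offset plane clipped inside the reference extent
  test_plane <- grid_mesh(6, 6, lx = 0.5, ly = 0.5, x0 = 0.25, y0 = 0.25)
  test_plane$vertices[, 3] <- 0.5
  d1 <- deviation_analysis(test_plane, g, 2000)
  expect_equal(d1$mean, 0.5, tolerance = 1e-9)
  expect_equal(d1$std, 0, tolerance = 1e-9)
})

test_that("deviation of concentric spheres matches the brute-force oracle", {
  s1 <- fixture_sphere20()
  s2 <- fixture_sphere20.5()
  set.seed(17)
  P <- sample_surface(s2, 150)
  kern <- closest_on_mesh(P, s1)$distance
  oracle <- brute_closest_dist(P, s1)
  expect_lt(max(abs(kern - unname(oracle))), 1e-9)
  set.seed(18)
  dv <- deviation_analysis(s2, s1, 20000)
  expect_lt(abs(dv$mean - 0.5), 0.02)
})

test_that("deviation is invariant under a common rigid motion", {
  s1 <- fixture_sphere20()
  s2 <- fixture_sphere20.5()
  R <- ctfootprint:::euler_rotation(1.1, 0.2, -0.5)
  tr <- c(100, -40, 12)
  set.seed(7)
  d_a <- deviation_analysis(s2, s1, 5000)
  set.seed(7)
  d_b <- deviation_analysis(transform_mesh(s2, R, tr),
                            transform_mesh(s1, R, tr), 5000)
  expect_equal(d_a$mean, d_b$mean, tolerance = 1e-9)
  expect_equal(d_a$std, d_b$std, tolerance = 1e-9)
})

test_that("deviation estimates are stable across independent samples", {
  s1 <- fixture_sphere20()
  s2 <- fixture_sphere20.5()
  set.seed(100)
  a <- deviation_analysis(s2, s1, 20000)$mean
  b <- deviation_analysis(s2, s1, 20000)$mean
  expect_lt(abs(a - b) / a, 0.02)
})

test_that("two half-spheres merge into a closed sphere", {
  s <- fixture_sphere20()
  z <- face_centroids(s)[, 3]
  top <- submesh(s, which(z >= 0))
  bot <- submesh(s, which(z < 0))
  expect_false(is_watertight(top))
  merged <- merge_and_clean(list(top, bot), smoothing_iters = 0L)
  expect_true(is_watertight(merged))
  expect_lt(rel_err(mesh_volume(merged), 4 / 3 * pi * 8000), 0.02)
})

test_that("merging a single clean mesh without smoothing is the identity", {
  m <- cube_mesh()
  out <- merge_and_clean(list(m), smoothing_iters = 0L)
  expect_identical(nrow(out$vertices), nrow(m$vertices))
  expect_identical(nrow(out$faces), nrow(m$faces))
  expect_equal(mesh_volume(out), mesh_volume(m), tolerance = 1e-12)
})

test_that("small holes are closed, large ones preserved", {
  s <- fixture_sphere20()
  fc <- face_centroids(s)
  hole <- which(sqrt(rowSums(sweep(fc, 2, c(0, 0, 20))^2)) < 2.5)
  open_m <- submesh(s, setdiff(seq_len(nrow(s$faces)), hole))
  expect_false(is_watertight(open_m))
  closed <- merge_and_clean(list(open_m), smoothing_iters = 0L)
  expect_true(is_watertight(closed))
  # a cap this large must not be hallucinated shut
  big_hole <- which(fc[, 3] > 10)
  open_big <- submesh(s, setdiff(seq_len(nrow(s$faces)), big_hole))
  still_open <- merge_and_clean(list(open_big), smoothing_iters = 0L,
                                hole_max_edges = 50L)
  expect_false(is_watertight(still_open))
})

test_that("smoothing conserves volume and improves fidelity of noisy data", {
  s <- fixture_sphere20()
  set.seed(77)
  noisy <- s
  noisy$vertices <- noisy$vertices +
    matrix(rnorm(length(noisy$vertices), sd = 0.3), ncol = 3)
  v0 <- mesh_volume(noisy)
  sm <- merge_and_clean(list(noisy), smoothing_iters = 20L)
  expect_lt(abs(mesh_volume(sm) - v0) / v0, 0.01)
  set.seed(78)
  d_noisy <- deviation_analysis(noisy, s, 8000)$mean
  set.seed(78)
  d_smooth <- deviation_analysis(sm, s, 8000)$mean
  expect_lt(d_smooth, d_noisy)
})
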