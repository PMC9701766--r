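test_that("voxelization counts volumes correctly", {
  cube <- mesh_box(c(10, 10, 10))
  vm <- voxelize(cube, voxel_size = 0.5)
  expect_lt(abs(sum(vm$occupancy) - 8000) / 8000, 0.02)
  sph <- mesh_uv_sphere(10, n_lat = 48, n_lon = 96)
  vs <- voxelize(sph, voxel_size = 0.6)
  expect_lt(abs(sum(vs$occupancy) * 0.6^3 - 4188.79) / 4188.79, 0.02)
  # translating mesh and grid together leaves the occupancy unchanged
  tr <- c(13.2, -4.1, 7.7)
  bb <- mesh_bbox(cube)
  bounds <- rbind(bb[1, ] - 0.6, bb[2, ] + 0.6)
  v0 <- voxelize(cube, voxel_size = 0.6, bounds = bounds)
  v1 <- voxelize(cube, rigid_transform(diag(3), tr), voxel_size = 0.6,
                 bounds = bounds + rbind(tr, tr))
  expect_identical(v0$occupancy, v1$occupancy)
  # open surfaces are rejected
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(voxelize(triangle_mesh(v, rbind(c(1, 2, 3)))), "watertight")
})

test_that("dice follows the set-overlap formula", {
  mask <- function(occ) structure(list(occupancy = occ, voxel_size = 1,
                                       origin = c(0, 0, 0)),
                                  class = "voxel_mask")
  x <- array(FALSE, c(10, 10, 2))
  x[1:10, 1:10, 1] <- TRUE           # |X| = 100
  y <- array(FALSE, c(10, 10, 2))
  y[1:5, 1:10, 1] <- TRUE            # |Y| = 50 nested in X
  y[1:5, 1:10, 2] <- TRUE            # plus 50 disjoint -> |Y| = 100
  expect_equal(dice(mask(x), mask(x)), 1.0)
  expect_equal(dice(mask(x), mask(y)), 2 * 50 / (100 + 100))
  z <- array(FALSE, c(10, 10, 2)); z[1, 1, 2] <- TRUE
  x2 <- array(FALSE, c(10, 10, 2)); x2[2:3, 1, 1] <- TRUE
  expect_equal(dice(mask(z), mask(x2)), 0.0)
  expect_error(dice(mask(x), mask(x[, , 1, drop = FALSE])), "grids")
  empty <- array(FALSE, c(10, 10, 2))
  expect_error(dice(mask(empty), mask(empty)), "empty")
  # symmetry on real meshes via a shared grid
  m <- fix_vertebra()
  vp <- voxelize_pair(m, transform_identity(), m,
                      rigid_transform(rot_x(3), c(1, 0.5, -1)), 0.6)
  expect_equal(dice(vp[[1]], vp[[2]]), dice(vp[[2]], vp[[1]]))
  expect_gt(dice(vp[[1]], vp[[2]]), 0.5)
  expect_lt(dice(vp[[1]], vp[[2]]), 1)
})

test_that("mean surface distance matches closed forms and the brute force", {
  m <- fix_vertebra()
  expect_lt(mean_surface_distance(m, m, samples_per_mm2 = 1, seed = 1), 1e-9)
  # two parallel unit squares 2 mm apart: constant distance field
  sq <- function(z) triangle_mesh(rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z),
                                        c(0, 1, z)),
                                  rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_lt(abs(mean_surface_distance(sq(0), sq(2), 50, seed = 2) - 2), 1e-6)
  expect_lt(abs(hausdorff_max(sq(0), sq(2), 50, seed = 2) - 2), 1e-6)
  # rigid invariance when both meshes move together
  m2 <- apply_transform(rigid_transform(rot_x(2), c(0.4, -0.2, 0.9)), m)
  g <- rigid_transform(rot_z(33) %*% rot_y(-12), c(100, -50, 30))
  d0 <- mean_surface_distance(m, m2, 2, seed = 3)
  d1 <- mean_surface_distance(apply_transform(g, m), apply_transform(g, m2),
                              2, seed = 3)
  expect_lt(abs(d0 - d1), 1e-6)
})

test_that("Metro estimate agrees with a dense nearest-point brute force", {
  m1 <- mesh_box(c(10, 10, 10))
  m2 <- apply_transform(rigid_transform(rot_x(3) %*% rot_z(2), c(1, 0.6, 1.8)),
                        mesh_box(c(10, 10, 10)))
  est <- mean_surface_distance(m1, m2, samples_per_mm2 = 10, seed = 4)
  # oracle: same query samples, distances to a dense point cloud on m2
  # (nearest-vertex brute force, independent of the point-triangle kernel)
  q <- sample_mesh_points(m1, 10, seed = 4)
  cloud <- sample_mesh_points(m2, 200, seed = 8)$points
  d_or <- vapply(seq_len(nrow(q$points)), function(i)
    sqrt(min(rowSums(sweep(cloud, 2, q$points[i, ], "-")^2))), numeric(1))
  oracle <- sum(d_or * q$weights) / sum(q$weights)
  expect_lt(abs(est - oracle) / oracle, 0.01)
  # convergence on the synthetic vertebra: doubling density moves it < 0.5%
  m <- make_vertebra(default_shape_params("L2", seed = 21))
  mp <- apply_transform(rigid_transform(rot_x(2.5), c(0.8, -0.5, 1.1)), m)
  e1 <- mean_surface_distance(m, mp, samples_per_mm2 = 2, seed = 6)
  e2 <- mean_surface_distance(m, mp, samples_per_mm2 = 4, seed = 7)
  expect_lt(abs(e2 - e1) / e1, 0.005)
  # Hausdorff dominates the mean
  expect_gte(hausdorff_max(m, mp, 2, seed = 7), e1)
})

test_that("point-to-mesh distance kernel is exact on a unit triangle", {
  V <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  F1 <- rbind(c(1L, 2L, 3L))
  d <- spinereg:::cpp_point_mesh_distance(
    rbind(c(0.5, 0.5, 1),     # above the face
          c(-1, -1, 0),       # beyond vertex a
          c(3, 0, 0),         # beyond vertex b along the edge
          c(1, -2, 0)),       # beyond edge ab
    V, F1)
  expect_equal(d, c(1, sqrt(2), 1, 2), tolerance = 1e-12)
})

test_that("ICC matches the pingouin reference on a fixture", {
  a <- c(41.2, 55.3, 48.9, 60.1, 44.7, 52.3, 38.6, 49.5)
  b <- c(42.8, 54.1, 50.2, 58.8, 45.9, 53.5, 40.1, 48.7)
  single <- icc(cbind(a, b), "single")
  meank <- icc(cbind(a, b), "mean_k")
  # reference values computed with pingouin.intraclass_corr (ICC(A,1)/(A,k))
  expect_lt(abs(single$estimate - 0.9817858747), 1e-3)
  expect_lt(abs(meank$estimate - 0.9908092365), 1e-3)
  expect_lt(abs(single$lower - 0.92), 0.01)
  expect_lt(abs(meank$lower - 0.96), 0.01)
  expect_true(single$upper <= 1 && meank$upper <= 1)
})

test_that("ICC recovers variance-component ground truth", {
  set.seed(99)
  n <- 200
  case_effect <- rnorm(n, sd = 3)        # between-case variance 9
  ratings <- cbind(case_effect + rnorm(n), case_effect + rnorm(n))
  est <- icc(ratings, "single")
  expect_lt(abs(est$estimate - 0.9), est$estimate - est$lower + 0.02)
  expect_gt(est$estimate, 0.85)
  expect_lt(est$estimate, 0.95)
  # unrelated raters: ICC near zero
  null <- icc(cbind(rnorm(n), rnorm(n)), "single")
  expect_lt(null$estimate, 0.2)
  # identical columns: perfect agreement
  same <- icc(cbind(case_effect, case_effect), "single")
  expect_equal(same$estimate, 1.0, tolerance = 1e-12)
})

test_that("degenerate ICC inputs are rejected", {
  expect_error(icc(cbind(rep(1, 10), rep(1, 10))), "variance")
  expect_error(icc(cbind(1:3, 2:4)), "5 cases")
  expect_error(icc(cbind(c(1:9, NA), 1:10)), "missing")
})
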