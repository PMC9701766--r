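test_that("point projection follows similar triangles", {
  env <- default_environment()  # SID 1800, object at SOD 1400
  # point on the source-principal-point axis projects to the principal point
  expect_equal(as.numeric(project_points(env$frontal, c(0, 0, 0))), c(0, 0),
               tolerance = 1e-12)
  # lateral offset x at the object plane magnifies by SID/SOD
  uv <- project_points(env$frontal, c(30, 0, 0))
  expect_equal(as.numeric(uv[1, "u"]), 30 * 1800 / 1400, tolerance = 1e-9)
  expect_equal(as.numeric(uv[1, "v"]), 0, tolerance = 1e-9)
  # cranial offset maps to +v in both views
  expect_gt(project_points(env$sagittal, c(0, 0, 50))[1, "v"], 0)
  # orthographic mode: offsets map 1:1
  env_o <- default_environment(orthographic = TRUE)
  expect_equal(as.numeric(project_points(env_o$frontal, c(30, 0, -12))),
               c(30, -12), tolerance = 1e-9)
  # ray parallel to the detector plane errors
  expect_error(project_points(env$frontal, c(0, 1400, 0) + c(5, 0, 0)),
               "parallel")
})

test_that("view and environment invariants are enforced", {
  expect_error(projection_view("frontal", c(0, 100, 0), c(0, -100, 0),
                               u = c(1, 0, 0), v = c(0.1, 0, 1)),
               "orthogonal")
  expect_error(default_environment(sid = 1000, sod = 1200), "SID > SOD")
  v1 <- projection_view("frontal", c(0, 1400, 0), c(0, -400, 0),
                        c(1, 0, 0), c(0, 0, 1))
  # 5-degree tilt about z: axes still orthonormal, planes no longer are
  v2 <- projection_view("sagittal", c(-1400, 0, 0), c(400, 0, 0),
                        c(sin(pi / 36), cos(pi / 36), 0), c(0, 0, 1))
  expect_error(biplanar_environment(v1, v2), "orthogonal")
})

test_that("sphere silhouettes match the cone-tangency closed form", {
  s <- mesh_uv_sphere(1, n_lat = 32, n_lon = 64)
  env_o <- default_environment(orthographic = TRUE)
  sil_o <- silhouette_contour(s, transform_identity(), env_o$frontal,
                              resolution = 0.02)
  expect_lt(abs(shoelace_area(sil_o$points) - pi) / pi, 0.02)
  # perspective: detector radius SID * r / sqrt(d^2 - r^2)
  s10 <- mesh_uv_sphere(10, n_lat = 48, n_lon = 96)
  env <- default_environment()
  sil <- silhouette_contour(s10, transform_identity(), env$frontal,
                            resolution = 0.2)
  r_obs <- sqrt(shoelace_area(sil$points) / pi)
  r_exp <- 1800 * 10 / sqrt(1400^2 - 10^2)
  expect_lt(abs(r_obs - r_exp) / r_exp, 0.02)
})

test_that("box silhouette is its cross-section under orthographic view", {
  b <- mesh_box(c(40, 20, 30))
  env_o <- default_environment(orthographic = TRUE)
  sil <- silhouette_contour(b, transform_identity(), env_o$frontal,
                            resolution = 0.25)
  p <- sil$points
  expect_lte(abs(diff(range(p[, 1])) - 40), 0.25 + 1e-9)
  expect_lte(abs(diff(range(p[, 2])) - 30), 0.25 + 1e-9)
  expect_lt(abs(shoelace_area(p) - 1200) / 1200, 0.02)
})

test_that("perspective magnifies a planar lamina by (SID/SOD)^2 in area", {
  # flat square at the object plane (y = 0 for the frontal view)
  v <- rbind(c(-10, 0, -10), c(10, 0, -10), c(10, 0, 10), c(-10, 0, 10))
  lam <- suppressWarnings(triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4))))
  env <- default_environment()
  sil <- silhouette_contour(lam, transform_identity(), env$frontal,
                            resolution = 0.1)
  mag2 <- (1800 / 1400)^2
  expect_lt(abs(shoelace_area(sil$points) - 400 * mag2) / (400 * mag2), 0.02)
  # orthographic projection leaves it unchanged regardless of distance
  env_o <- default_environment(orthographic = TRUE)
  for (shift in c(0, 200)) {
    silo <- silhouette_contour(lam,
                               rigid_transform(diag(3), c(0, shift, 0)),
                               env_o$frontal, resolution = 0.1)
    expect_lt(abs(shoelace_area(silo$points) - 400) / 400, 0.02)
  }
})

test_that("silhouette area converges with resolution", {
  s <- mesh_uv_sphere(10, n_lat = 48, n_lon = 96)
  env <- default_environment()
  a <- vapply(c(0.8, 0.2), function(res)
    shoelace_area(silhouette_contour(s, transform_identity(), env$frontal,
                                     res)$points), numeric(1))
  r_exp <- 1800 * 10 / sqrt(1400^2 - 100)
  expect_lt(abs(a[2] - pi * r_exp^2) / (pi * r_exp^2), 0.02)
  expect_lt(abs(a[2] - pi * r_exp^2), abs(a[1] - pi * r_exp^2) + 1e-9)
})

test_that("radiograph rendering is binary, deterministic and seedable", {
  sp <- fix_spine()
  env <- fix_env()
  view <- projection_view("frontal", env$frontal$source, env$frontal$origin,
                          env$frontal$u, env$frontal$v,
                          pixel_spacing = 1.5, size = c(300, 300))
  img <- render_silhouette_radiograph(sp, view)
  expect_setequal(unique(as.numeric(img$pixels)), c(0, 1))
  img_n1 <- render_silhouette_radiograph(sp, view, noise_sd = 0.05, seed = 9)
  img_n2 <- render_silhouette_radiograph(sp, view, noise_sd = 0.05, seed = 9)
  expect_identical(img_n1$pixels, img_n2$pixels)
  expect_false(identical(img_n1$pixels, img$pixels))
  # empty scene renders a uniform background
  empty <- render_silhouette_radiograph(list(), view)
  expect_true(all(empty$pixels == 0))
})

test_that("place_environment shifts projections geometrically", {
  env <- fix_env()
  p <- c(12, -7, 130)
  uv0 <- project_points(env$frontal, p)
  env2 <- place_environment(env, z_offset = 50)
  uv1 <- project_points(env2$frontal, p)
  # oracle: shifting the environment +50 equals shifting the point -50
  uv_oracle <- project_points(env$frontal, p - c(0, 0, 50))
  expect_equal(as.numeric(uv1), as.numeric(uv_oracle), tolerance = 1e-9)
  expect_equal(uv1[1, "u"], uv0[1, "u"], tolerance = 1e-9)
  # zero offsets are the identity, and orthogonality is preserved
  env3 <- place_environment(env, 0, c(0, 0))
  expect_equal(env3$frontal$source, env$frontal$source)
  env4 <- place_environment(env, 30, c(5, -4))
  expect_s3_class(env4, "biplanar_environment")  # constructor re-checks
})

test_that("environment JSON and radiograph PNG round-trip", {
  env <- fix_env()
  path <- withr::local_tempfile(fileext = ".json")
  write_environment_json(env, path)
  back <- read_environment_json(path)
  expect_equal(back$frontal$source, env$frontal$source)
  expect_equal(back$sagittal$u, env$sagittal$u)
  expect_equal(back$frontal$pixel_spacing, env$frontal$pixel_spacing)
  img <- radiograph_image(matrix(seq(0, 1, length.out = 64), 8, 8), 0.5,
                          "frontal")
  png_path <- withr::local_tempfile(fileext = ".png")
  write_radiograph_png(img, png_path)
  back_img <- read_radiograph_png(png_path, 0.5, "frontal")
  expect_equal(back_img$pixels, img$pixels, tolerance = 1 / 255)
})
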