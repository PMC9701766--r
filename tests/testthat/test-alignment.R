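# 4-connected component count of a binary image
label_components <- function(px) {
  lab <- matrix(0L, nrow(px), ncol(px))
  cur <- 0L
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (px[i, j] > 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        q <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          r <- q[1] + d[1]; c <- q[2] + d[2]
          if (r >= 1 && r <= nrow(px) && c >= 1 && c <= ncol(px) &&
              px[r, c] > 0 && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  cur
}

test_that("midsagittal plane sits on the symmetry plane and follows shifts", {
  sp <- fix_spine()
  pl <- midsagittal_plane(sp)
  expect_equal(pl$normal, c(1, 0, 0))
  expect_lt(abs(pl$origin[1]), 0.1)  # symmetric model: plane at x = 0
  # lateral translation of the whole spine shifts the plane equally
  sp2 <- sp
  for (l in vertebra_labels()) {
    p <- sp2$vertebrae[[l]]$pose
    sp2$vertebrae[[l]]$pose <- rigid_transform(p$R, p$t + c(7, 0, 0))
  }
  expect_equal(midsagittal_plane(sp2)$origin[1], pl$origin[1] + 7,
               tolerance = 1e-9)
})

test_that("plane offset matches the brute-force min/max midpoint", {
  sp <- fix_spine()
  # asymmetric decoy: elongate one transverse process region
  sp$vertebrae[["L3"]]$mesh$vertices[, 1] <-
    sp$vertebrae[["L3"]]$mesh$vertices[, 1] * 1.4
  xs <- unlist(lapply(vertebra_labels(), function(l) {
    v <- sp$vertebrae[[l]]
    sel <- v$mesh$regions == "body"
    idx <- unique(as.vector(v$mesh$faces[sel, , drop = FALSE]))
    apply_transform(v$pose, v$mesh$vertices[idx, , drop = FALSE])[, 1]
  }))
  expect_equal(midsagittal_plane(sp)$origin[1], (min(xs) + max(xs)) / 2,
               tolerance = 1e-12)
})

test_that("section image rasters the mid-plane cut", {
  # plane through a unit cube center: filled square of side 1
  cube_sp <- structure(list(vertebrae = stats::setNames(lapply(
    vertebra_labels(), function(l)
      list(mesh = mesh_box(c(1, 1, 1), label = l, region = "body"),
           pose = rigid_transform(diag(3),
                                  c(0, 0, 2 * match(l, vertebra_labels()))))),
    vertebra_labels())), class = "spine_model")
  sec <- section_image(cube_sp, list(origin = c(0, 0, 0), normal = c(1, 0, 0)),
                       pixel_spacing = 0.05)
  area <- sum(sec$pixels) * sec$pixel_spacing^2
  expect_lt(abs(area - 6 * 1), 6 * 2 * 0.05)  # six unit squares
  # straight spine: six disjoint filled components
  sp <- fix_spine()
  sec2 <- section_image(sp, pixel_spacing = 1)
  comp <- label_components(sec2$pixels)
  expect_equal(comp, 6L)
  expect_error(section_image(sp, list(origin = c(500, 0, 0),
                                      normal = c(1, 0, 0))),
               "intersect")
  expect_error(section_image(sp, list(origin = c(0, 0, 0),
                                      normal = c(0.5, 0.5, 0))),
               "normal")
})

test_that("section area estimates converge with resolution", {
  sp <- fix_spine()
  a <- vapply(c(1, 0.5), function(px)
    sum(section_image(sp, pixel_spacing = px)$pixels) * px^2, numeric(1))
  expect_lt(abs(a[2] - a[1]) / a[1], 0.01)
})

test_that("endplate lines report rigid rotations and wedges", {
  shapes <- list()
  for (l in vertebra_labels())
    shapes[[l]] <- vertebra_shape_params(
      wedge_angle = 0, seed = match(l, vertebra_labels()),
      caudal_block = l == "S")
  sp <- assemble_spine(shapes, sagittal_plan(rep(0, 5)))
  for (route in c("mesh", "section")) {
    expect_lt(abs(endplate_line(sp, "L3", "cranial", route)), 0.2)
    expect_lt(abs(endplate_line(sp, "L3", "caudal", route)), 0.2)
  }
  # rigid rotation of one vertebra moves its endplate line by the same angle
  v <- sp$vertebrae[["L2"]]
  ctr <- as.numeric(apply_transform(v$pose, mesh_centroid(v$mesh)))
  Rp <- rot_x(12)
  sp$vertebrae[["L2"]]$pose <- compose_transforms(
    rigid_transform(Rp, ctr - as.numeric(Rp %*% ctr)), v$pose)
  expect_lt(abs(endplate_line(sp, "L2", "cranial", "mesh") - 12), 0.2)
  # wedge: cranial vs caudal difference equals the wedge angle
  m8 <- make_vertebra(vertebra_shape_params(wedge_angle = 8, seed = 3))
  single <- structure(list(vertebrae = list(
    L1 = list(mesh = m8, pose = transform_identity()))),
    class = "spine_model")
  d <- endplate_line(single, "L1", "cranial", "mesh") -
    endplate_line(single, "L1", "caudal", "mesh")
  expect_lt(abs(d - 8), 0.3)
})

test_that("mesh and section angle routes agree within half a degree", {
  sp <- fix_spine()
  am <- compute_angles(sp, route = "mesh")
  as_ <- compute_angles(sp, route = "section")
  expect_lt(max(abs(am$intersegmental - as_$intersegmental)), 0.5)
  expect_lt(abs(am$LL - as_$LL), 0.5)
})

test_that("angles are invariant under whole-body rigid motion", {
  sp <- fix_spine()
  a0 <- compute_angles(sp, route = "mesh")
  g <- rigid_transform(rot_x(-15) %*% rot_z(2), c(10, -20, 35))
  sp2 <- sp
  for (l in vertebra_labels())
    sp2$vertebrae[[l]]$pose <- compose_transforms(g, sp$vertebrae[[l]]$pose)
  a1 <- compute_angles(sp2, route = "mesh")
  expect_lt(max(abs(a0$intersegmental - a1$intersegmental)), 0.2)
  expect_lt(abs(a0$LL - a1$LL), 0.2)
})

test_that("angle differences are absolute, symmetric and zero on equality", {
  a <- angle_set(c(2, 5, 7, 10, 12.6), 45)
  b <- angle_set(c(3, 4, 7, 11, 12.6), 50.6)
  expect_equal(angle_abs_diff(a, a)$LL, 0)
  expect_true(all(angle_abs_diff(a, a)$intersegmental == 0))
  d1 <- angle_abs_diff(a, b)
  d2 <- angle_abs_diff(b, a)
  expect_equal(d1$intersegmental, d2$intersegmental)
  expect_equal(d1$LL, 5.6)  # the supine-to-standing lordosis effect size
})
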