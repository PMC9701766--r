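step_edge_image <- function(edge_u = 10, spacing = 0.5, n = 101) {
  # vertical intensity step at u = edge_u mm; image centered on 0
  px <- matrix(0, n, n)
  u <- ((seq_len(n)) - (n + 1) / 2) * spacing
  px[, u > edge_u] <- 1
  radiograph_image(px, spacing, "frontal")
}

test_that("contour2d validates and deduplicates points", {
  expect_error(contour2d(rbind(c(0, 0))), "at least")
  expect_error(contour2d(rbind(c(0, 0), c(1, 0)), closed = TRUE), "at least")
  c1 <- contour2d(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 0)),
                  closed = TRUE)
  expect_equal(nrow(c1$points), 3L)  # duplicate + closing point removed
})

test_that("point-to-contour distance matches geometry and brute force", {
  seg <- contour2d(rbind(c(-1, 0), c(1, 0)))
  expect_equal(point_to_contour_distance(c(0, 1), seg), 1.0)
  expect_equal(point_to_contour_distance(c(-1, 0), seg), 0.0)
  expect_equal(point_to_contour_distance(c(3, 0), seg), 2.0)
  # brute-force nearest-vertex oracle on a dense resampling
  set.seed(3)
  poly <- contour2d(cbind(10 * cos(seq(0, 2 * pi, length.out = 40)[-40]),
                          6 * sin(seq(0, 2 * pi, length.out = 40)[-40])),
                    closed = TRUE)
  dense <- densify_contour(poly, 0.02)
  for (i in 1:25) {
    p <- runif(2, -14, 14)
    d <- point_to_contour_distance(p, poly)
    d_oracle <- min(sqrt(rowSums(sweep(dense$points, 2, p, "-")^2)))
    expect_lt(abs(d - d_oracle), 0.02 / 2)
  }
})

test_that("distances are invariant under rigid motion of point and contour", {
  set.seed(11)
  poly <- contour2d(matrix(runif(16, -5, 5), ncol = 2))
  p <- c(1.5, -2)
  d0 <- point_to_contour_distance(p, poly)
  for (i in 1:10) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tr <- runif(2, -20, 20)
    poly2 <- contour2d(sweep(poly$points %*% t(R), 2, tr, "+"))
    p2 <- as.numeric(R %*% p + tr)
    expect_lt(abs(point_to_contour_distance(p2, poly2) - d0), 1e-9)
  }
})

test_that("sub-contour extraction respects ranges and counts", {
  sil <- contour2d(cbind(cos(seq(0, 2 * pi, length.out = 101)[-101]),
                         sin(seq(0, 2 * pi, length.out = 101)[-101])),
                   closed = TRUE, label = "L3")
  full <- contour_from_silhouette(sil, list(c(1, 100)))
  expect_true(full[[1]]$closed)
  expect_equal(nrow(full[[1]]$points), 100L)
  two <- contour_from_silhouette(sil, list(c(1, 20), c(51, 90)))
  expect_length(two, 2L)
  expect_false(any(vapply(two, `[[`, logical(1), "closed")))
  expect_equal(sum(vapply(two, function(c) nrow(c$points), integer(1))), 60L)
  expect_equal(two[[1]]$label, "L3")
  # wrap-around range
  wrap <- contour_from_silhouette(sil, list(c(95, 104)))
  expect_equal(nrow(wrap[[1]]$points), 10L)
  expect_error(contour_from_silhouette(sil, list(c(1, 20), c(10, 30))),
               "overlap")
  expect_error(contour_from_silhouette(sil, list(c(0, 5))), "invalid")
})

test_that("snapping leaves a uniform image untouched", {
  img <- radiograph_image(matrix(0.5, 81, 81), 0.5)
  cp <- rbind(c(-10, -5), c(0, 0), c(10, 5))
  sn <- snap_contour(img, cp, search_radius = 3, densify_step = 0.5,
                     mode = "linear")
  base <- densify_contour(contour2d(cp), 0.5)
  expect_equal(sn$points, base$points, tolerance = 1e-9)
  expect_error(snap_contour(img, rbind(c(100, 0)), 3), "outside")
})

test_that("samples snap onto a step edge within half a pixel", {
  # pixels switch between centers 10.0 and 10.5, so the edge sits at 10.25
  img <- step_edge_image(edge_u = 10, spacing = 0.5)
  cp <- rbind(c(11, -15), c(11, 0), c(11, 15))  # offset control points
  sn <- snap_contour(img, cp, search_radius = 3, densify_step = 0.5,
                     mode = "linear")
  expect_lte(max(abs(sn$points[, 1] - 10.25)), 0.25 + 1e-9)
  # control points already on the edge barely move
  cp2 <- rbind(c(10.25, -15), c(10.25, 0), c(10.25, 15))
  sn2 <- snap_contour(img, cp2, search_radius = 3, densify_step = 0.5,
                      mode = "linear")
  expect_lte(max(abs(sn2$points[, 1] - 10.25)), 0.25 + 1e-9)
})

test_that("snapping is idempotent within half a pixel", {
  img <- step_edge_image(edge_u = 5, spacing = 0.5)
  cp <- rbind(c(5.7, -12), c(5.7, 0), c(5.7, 12))
  s1 <- snap_contour(img, cp, search_radius = 3, densify_step = 1,
                     mode = "linear")
  s2 <- snap_contour(img, s1$points, search_radius = 3, densify_step = 1,
                     mode = "linear")
  n <- min(nrow(s1$points), nrow(s2$points))
  moved <- sqrt(rowSums((s2$points[1:n, ] - s1$points[1:n, ])^2))
  expect_lt(max(moved), 0.25 + 1e-9)
})

test_that("contours round-trip through JSON", {
  cs <- list(contour2d(rbind(c(0, 0), c(1, 2.5)), label = "L1",
                       view = "frontal"),
             contour2d(rbind(c(0, 0), c(1, 0), c(1, 1)), closed = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_contours_json(cs, path)
  back <- read_contours_json(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$points, cs[[1]]$points, tolerance = 1e-12)
  expect_equal(back[[1]]$label, "L1")
  expect_true(back[[2]]$closed)
})
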