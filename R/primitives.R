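#' Primitive closed meshes
#'
#' Axis-aligned box and latitude/longitude sphere meshes, used as analytic
#' fixtures (projection and metric checks) and as building blocks of the
#' synthetic vertebrae. Both are watertight with outward normals.
#'
#' @param size length-3 extents (mm) of the box.
#' @param center length-3 center (mm).
#' @param radius sphere radius (mm).
#' @param n_lat,n_lon sphere tessellation (latitude bands, longitude steps).
#' @param label optional vertebral label.
#' @param region optional region tag applied to all faces.
#' @return A `triangle_mesh`.
#' @export
mesh_box <- function(size = c(1, 1, 1), center = c(0, 0, 0),
                     label = NULL, region = NULL) {
  h <- size / 2
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  v <- sweep(sweep(sgn, 2, h, "*"), 2, center, "+")
  # vertex order from expand.grid: x fastest, then y, then z
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(1, 3, 4, 2),  # z-  (viewed from below: outward -z)
    quad(5, 6, 8, 7),  # z+
    quad(1, 2, 6, 5),  # y-
    quad(3, 7, 8, 4),  # y+
    quad(1, 5, 7, 3),  # x-
    quad(2, 4, 8, 6))  # x+
  m <- triangle_mesh(v, f, label = label,
                     regions = if (is.null(region)) NULL else rep(region, 12))
  ensure_outward(m)
}

#' @rdname mesh_box
#' @export
mesh_uv_sphere <- function(radius = 1, center = c(0, 0, 0),
                           n_lat = 24, n_lon = 48) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  g <- expand.grid(lon = lon, lat = lat)
  ring <- cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon), sin(g$lat))
  v <- rbind(c(0, 0, -1), ring, c(0, 0, 1)) * radius
  v <- sweep(v, 2, center, "+")
  idx <- function(i, j) 1L + (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  f <- list()
  for (j in seq_len(n_lon)) {
    f[[length(f) + 1L]] <- c(1L, idx(1, j + 1), idx(1, j))
    f[[length(f) + 1L]] <- c(nrow(v), idx(n_lat - 1, j), idx(n_lat - 1, j + 1))
  }
  for (i in seq_len(n_lat - 2)) {
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j + 1); d <- idx(i + 1, j)
      f[[length(f) + 1L]] <- c(a, b, c)
      f[[length(f) + 1L]] <- c(a, c, d)
    }
  }
  ensure_outward(triangle_mesh(v, do.call(rbind, f)))
}

# Flip faces of any closed component whose signed volume is negative,
# so normals point outward.
ensure_outward <- function(mesh) {
  comp <- mesh_components(mesh)
  for (k in seq_len(max(comp))) {
    sel <- comp == k
    f <- mesh$faces[sel, , drop = FALSE]
    p1 <- mesh$vertices[f[, 1], , drop = FALSE]
    p2 <- mesh$vertices[f[, 2], , drop = FALSE]
    p3 <- mesh$vertices[f[, 3], , drop = FALSE]
    v6 <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
              p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
              p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]))
    if (v6 < 0) mesh$faces[sel, ] <- f[, c(1, 3, 2)]
  }
  mesh
}
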