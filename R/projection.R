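#' Calibrated projection view (simulated radiation source + detector)
#'
#' A central (perspective) projection defined by a point source and a
#' planar detector spanned by two orthonormal axes `u`, `v`; detector
#' coordinates are expressed in mm with the origin at the principal point
#' (detector center). An orthographic mode (parallel rays along the
#' detector normal) is provided for analytic tests.
#'
#' Default biplanar geometry: source-to-image distance (SID) 1800 mm with
#' the object centered at source-to-object distance (SOD) 1400 mm; the
#' frontal view projects along -y (source anterior) with u = patient-left,
#' the sagittal view along +x (source patient-right) with u = anterior;
#' v = cranial in both. Image row 1 is the most cranial row (raster y-down
#' corresponds to geometry v-up).
#'
#' @param name view name, `"frontal"` or `"sagittal"`.
#' @param source 3D source position (mm).
#' @param detector_origin 3D detector center = principal point (mm).
#' @param u,v orthonormal in-plane detector axes.
#' @param pixel_spacing detector sampling (mm/px).
#' @param size image size in pixels, `c(nx, ny)`.
#' @param orthographic logical; parallel projection along the
#'   source-to-detector direction.
#' @return An object of class `projection_view`.
#' @export
projection_view <- function(name, source, detector_origin, u, v,
                            pixel_spacing = 0.5, size = c(900, 900),
                            orthographic = FALSE) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  if (abs(sum(u * v)) > 1e-9) stop("detector axes u and v must be orthogonal")
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (abs(sum((source - detector_origin) * n)) < 1e-9)
    stop("source must not lie on the detector plane")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  structure(list(name = name, source = as.numeric(source),
                 origin = as.numeric(detector_origin),
                 u = u, v = v, normal = n,
                 pixel_spacing = pixel_spacing,
                 size = as.integer(size),
                 orthographic = isTRUE(orthographic)),
            class = "projection_view")
}

#' @export
print.projection_view <- function(x, ...) {
  cat(sprintf("<projection_view %s> %s, SID %.0f mm, %d x %d px @ %.2f mm\n",
              x$name, if (x$orthographic) "orthographic" else "perspective",
              sqrt(sum((x$source - x$origin)^2)),
              x$size[1], x$size[2], x$pixel_spacing))
  invisible(x)
}

#' Biplanar environment of two mutually orthogonal views
#'
#' @param frontal,sagittal `projection_view` objects; their detector
#'   planes must be orthogonal within 0.1 degree.
#' @return An object of class `biplanar_environment`.
#' @export
biplanar_environment <- function(frontal, sagittal) {
  ang <- .rad2deg(acos(pmin(1, abs(sum(frontal$normal * sagittal$normal)))))
  if (abs(ang - 90) > 0.1)
    stop(sprintf("detector planes must be orthogonal (angle %.3f deg)", ang))
  structure(list(frontal = frontal, sagittal = sagittal),
            class = "biplanar_environment")
}

#' @rdname biplanar_environment
#' @param sid,sod source-to-image and source-to-object distances (mm).
#' @param pixel_spacing detector sampling (mm/px).
#' @param size image size `c(nx, ny)` px.
#' @param center world point the environment is centered on (mm).
#' @param orthographic build both views in orthographic mode.
#' @export
default_environment <- function(sid = 1800, sod = 1400, pixel_spacing = 0.5,
                                size = c(900, 900), center = c(0, 0, 0),
                                orthographic = FALSE) {
  if (!(sid > sod && sod > 0)) stop("need SID > SOD > 0")
  frontal <- projection_view(
    "frontal",
    source = center + c(0, sod, 0),
    detector_origin = center + c(0, sod - sid, 0),
    u = c(1, 0, 0), v = c(0, 0, 1),
    pixel_spacing = pixel_spacing, size = size, orthographic = orthographic)
  sagittal <- projection_view(
    "sagittal",
    source = center + c(-sod, 0, 0),
    detector_origin = center + c(sid - sod, 0, 0),
    u = c(0, 1, 0), v = c(0, 0, 1),
    pixel_spacing = pixel_spacing, size = size, orthographic = orthographic)
  biplanar_environment(frontal, sagittal)
}

#' Shift a biplanar environment (manual X-ray registration step)
#'
#' Translates both detectors and sources rigidly, mostly along the
#' cranio-caudal (z) axis; done once per case so that repeated
#' registrations share one coordinate system.
#'
#' @param env a `biplanar_environment`.
#' @param z_offset cranio-caudal shift (mm).
#' @param in_plane_offsets length-2 shift in the transverse plane
#'   `c(x, y)` (mm).
#' @return The shifted environment.
#' @export
place_environment <- function(env, z_offset = 0, in_plane_offsets = c(0, 0)) {
  d <- c(in_plane_offsets[1], in_plane_offsets[2], z_offset)
  shift <- function(view) {
    view$source <- view$source + d
    view$origin <- view$origin + d
    view
  }
  biplanar_environment(shift(env$frontal), shift(env$sagittal))
}

#' @export
apply_transform.projection_view <- function(transform, x) {
  x$source <- as.numeric(apply_transform(transform, x$source))
  x$origin <- as.numeric(apply_transform(transform, x$origin))
  x$u <- as.numeric(transform$R %*% x$u)
  x$v <- as.numeric(transform$R %*% x$v)
  x$normal <- as.numeric(transform$R %*% x$normal)
  x
}

#' @export
apply_transform.biplanar_environment <- function(transform, x) {
  biplanar_environment(apply_transform(transform, x$frontal),
                       apply_transform(transform, x$sagittal))
}

#' Project 3D points onto a detector
#'
#' Central projection from the source through each point onto the detector
#' plane (or parallel projection in orthographic mode), returned in (u, v)
#' detector mm coordinates.
#'
#' @param view a `projection_view`.
#' @param points n x 3 matrix (or length-3 vector) of world points (mm).
#' @return n x 2 matrix of detector coordinates (mm).
#' @export
project_points <- function(view, points) {
  p <- rbind(points)
  rel <- sweep(p, 2, view$source, "-")
  if (view$orthographic) {
    dirn <- view$origin - view$source
    dirn <- dirn / sqrt(sum(dirn^2))
    lam <- as.numeric((sweep(p, 2, view$origin, "-") %*% view$normal)) /
      sum(dirn * view$normal)
    hit <- p - outer(lam, dirn)
  } else {
    dn <- as.numeric(rel %*% view$normal)
    if (any(abs(dn) < 1e-12))
      stop("ray parallel to the detector plane")
    lam <- as.numeric(sum((view$origin - view$source) * view$normal)) / dn
    hit <- sweep(outer(lam, c(1, 1, 1)) * rel, 2, view$source, "+")
  }
  rel2 <- sweep(hit, 2, view$origin, "-")
  cbind(u = as.numeric(rel2 %*% view$u), v = as.numeric(rel2 %*% view$v))
}

# mm <-> continuous pixel coordinates on a view's raster.
# Pixel centers at integer (col, row); col 1..nx maps u, row 1..ny maps v
# with row 1 the most cranial (largest v).
det_mm_to_px <- function(uv, spacing, size) {
  cbind(col = uv[, 1] / spacing + (size[1] + 1) / 2,
        row = (size[2] + 1) / 2 - uv[, 2] / spacing)
}

det_px_to_mm <- function(px, spacing, size) {
  cbind(u = (px[, 1] - (size[1] + 1) / 2) * spacing,
        v = ((size[2] + 1) / 2 - px[, 2]) * spacing)
}

# Rasterize the projected footprint of world-frame meshes on an arbitrary
# grid given in pixel units; returns the [ix, iy] 0/1 matrix plus the grid.
rasterize_footprint <- function(meshes, view, resolution, bbox_mm = NULL,
                                margin = 2) {
  uv_all <- lapply(meshes, function(m) project_points(view, m$vertices))
  if (is.null(bbox_mm)) {
    allp <- do.call(rbind, uv_all)
    bbox_mm <- rbind(apply(allp, 2, min) - margin, apply(allp, 2, max) + margin)
  }
  nx <- max(2L, ceiling((bbox_mm[2, 1] - bbox_mm[1, 1]) / resolution) + 1L)
  ny <- max(2L, ceiling((bbox_mm[2, 2] - bbox_mm[1, 2]) / resolution) + 1L)
  ux <- bbox_mm[1, 1] + (seq_len(nx) - 1) * resolution
  vy <- bbox_mm[1, 2] + (seq_len(ny) - 1) * resolution
  mask <- matrix(0L, nx, ny)
  for (k in seq_along(meshes)) {
    m <- meshes[[k]]
    uv <- uv_all[[k]]
    px <- cbind((uv[, 1] - bbox_mm[1, 1]) / resolution + 1,
                (uv[, 2] - bbox_mm[1, 2]) / resolution + 1)
    tri <- cbind(px[m$faces[, 1], , drop = FALSE],
                 px[m$faces[, 2], , drop = FALSE],
                 px[m$faces[, 3], , drop = FALSE])
    mask <- mask | cpp_fill_triangles(tri, nx, ny)
  }
  list(mask = mask + 0L, ux = ux, vy = vy)
}

#' Projected silhouette contour of a posed mesh
#'
#' The closed outer boundary of the mesh's projected footprint on the
#' detector, obtained by rasterizing the footprint at `resolution` and
#' tracing the 0.5-level boundary (marching squares); the outermost (largest
#' area) boundary polygon is returned in detector mm coordinates.
#'
#' @param mesh a `triangle_mesh` (local frame).
#' @param pose `rigid_transform` placing the mesh in the world.
#' @param view a `projection_view`.
#' @param resolution raster step (mm/px) controlling boundary accuracy.
#' @return A closed [contour2d()].
#' @export
silhouette_contour <- function(mesh, pose, view, resolution = 0.5) {
  world <- apply_transform(pose, mesh)
  ras <- rasterize_footprint(list(world), view, resolution)
  if (!any(ras$mask > 0)) stop("empty projection: mesh footprint off-detector")
  cl <- grDevices::contourLines(ras$ux, ras$vy, ras$mask, levels = 0.5)
  if (length(cl) == 0) stop("empty projection: no silhouette boundary")
  area <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2)
  }, numeric(1))
  best <- cl[[which.max(area)]]
  contour2d(cbind(best$x, best$y), closed = TRUE, label = mesh$label,
            view = view$name)
}

#' Render a synthetic silhouette radiograph
#'
#' Binary union footprint of all vertebrae of a spine model on the full
#' detector raster, optionally Gaussian-blurred and with additive Gaussian
#' noise (clamped to [0, 1]); deterministic given `seed`.
#'
#' @param spine a `spine_model` (or list of world-frame meshes).
#' @param view a `projection_view`.
#' @param noise_sd additive Gaussian noise standard deviation (grayscale
#'   units, image scale 0..1).
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param seed integer seed for the noise.
#' @return A `radiograph_image` (pixels matrix, row 1 most cranial).
#' @export
render_silhouette_radiograph <- function(spine, view, noise_sd = 0,
                                         blur_sigma = 0, seed = NULL) {
  meshes <- if (inherits(spine, "spine_model")) {
    lapply(vertebra_labels(), function(l) posed_mesh(spine, l))
  } else spine
  nx <- view$size[1]; ny <- view$size[2]
  half_u <- (nx - 1) / 2 * view$pixel_spacing
  half_v <- (ny - 1) / 2 * view$pixel_spacing
  if (length(meshes) == 0) {
    mask <- matrix(0L, nx, ny)
  } else {
    ras <- rasterize_footprint(meshes, view, view$pixel_spacing,
                               bbox_mm = rbind(c(-half_u, -half_v),
                                               c(half_u, half_v)))
    mask <- ras$mask[seq_len(nx), seq_len(ny), drop = FALSE]
  }
  img <- t(mask)[ny:1, , drop = FALSE] * 1.0  # rows: v descending (cranial first)
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
    img <- pmin(1, pmax(0, img))
  }
  radiograph_image(img, view$pixel_spacing, view$name)
}

#' Radiograph image container
#'
#' @param pixels numeric matrix in [0, 1]; row 1 is the most cranial row.
#' @param pixel_spacing mm per pixel.
#' @param view view name.
#' @return An object of class `radiograph_image`.
#' @export
radiograph_image <- function(pixels, pixel_spacing, view = NULL) {
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  structure(list(pixels = as.matrix(pixels), pixel_spacing = pixel_spacing,
                 view = view), class = "radiograph_image")
}

#' @export
print.radiograph_image <- function(x, ...) {
  cat(sprintf("<radiograph_image %s> %d x %d px @ %.2f mm\n",
              x$view %||% "?", ncol(x$pixels), nrow(x$pixels),
              x$pixel_spacing))
  invisible(x)
}

#' @export
plot.radiograph_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, nrow(x$pixels):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable Gaussian blur, sigma in pixels; edges renormalized.
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
      wt[ok, ] <- wt[ok, ] + k[j]
    }
    out / wt
  }
  t(conv1(t(conv1(img))))
}
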