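#' 2D contour on a detector plane
#'
#' An ordered polyline (open) or polygon (closed) in detector mm
#' coordinates, optionally tagged with a vertebral label and view name.
#' Consecutive duplicate points are removed. Multi-segment contour objects
#' (several open polylines sharing one label, as produced by selecting
#' only the well-defined vertebral edges) are plain lists of `contour2d`
#' objects; all contour consumers accept either form.
#'
#' @param points n x 2 matrix of (u, v) detector coordinates (mm).
#' @param closed logical; closed polygons need >= 3 points, open
#'   polylines >= 2.
#' @param label optional vertebral label.
#' @param view optional view name.
#' @return An object of class `contour2d`.
#' @export
contour2d <- function(points, closed = FALSE, label = NULL, view = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  if (nrow(points) > 1) {
    d <- rowSums((points[-1, , drop = FALSE] -
                  points[-nrow(points), , drop = FALSE])^2)
    points <- points[c(TRUE, d > 1e-18), , drop = FALSE]
  }
  if (closed && nrow(points) > 2 &&
      sum((points[1, ] - points[nrow(points), ])^2) < 1e-18)
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < (if (closed) 3L else 2L))
    stop("contour needs at least ", if (closed) 3 else 2, " distinct points")
  structure(list(points = unname(points), closed = isTRUE(closed),
                 label = label, view = view), class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("<contour2d%s%s> %d points, %s\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              if (is.null(x$view)) "" else paste0(" (", x$view, ")"),
              nrow(x$points), if (x$closed) "closed" else "open"))
  invisible(x)
}

#' @export
plot.contour2d <- function(x, add = FALSE, ...) {
  p <- x$points
  if (x$closed) p <- rbind(p, p[1, ])
  if (!add) graphics::plot(p, type = "l", asp = 1, xlab = "u (mm)",
                           ylab = "v (mm)", ...)
  else graphics::lines(p, ...)
  invisible(x)
}

# Coerce a contour or list of contours to a list of contour2d.
as_contour_list <- function(x) {
  if (inherits(x, "contour2d")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, logical(1), "contour2d"))) x
  else stop("expected a contour2d or a list of contour2d")
}

#' Resample a contour at a fixed arc-length step
#'
#' @param contour a `contour2d`.
#' @param step target spacing (mm).
#' @return A `contour2d` with (approximately) equally spaced points.
#' @export
densify_contour <- function(contour, step) {
  p <- contour$points
  if (contour$closed) p <- rbind(p, p[1, ])
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n <- max(if (contour$closed) 3L else 2L, ceiling(total / step) + 1L)
  si <- seq(0, total, length.out = n)
  if (contour$closed) si <- si[-n]
  ui <- stats::approx(s, p[, 1], xout = si)$y
  vi <- stats::approx(s, p[, 2], xout = si)$y
  contour2d(cbind(ui, vi), closed = contour$closed, label = contour$label,
            view = contour$view)
}

#' Distance from a point to a contour
#'
#' Euclidean distance to the nearest point on any segment of the contour
#' (polyline segments, not just vertices). Accepts a single contour or a
#' multi-segment contour list.
#'
#' @param p length-2 point or n x 2 matrix (mm).
#' @param contour a `contour2d` or list of them.
#' @return numeric vector of distances (mm).
#' @export
point_to_contour_distance <- function(p, contour) {
  p <- rbind(p)
  segs <- contour_segments(contour)
  a <- segs$a; b <- segs$b
  ab <- b - a
  len2 <- rowSums(ab^2)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    ap <- sweep(a, 2, p[i, ], "-")
    t0 <- pmin(1, pmax(0, -rowSums(ap * ab) / pmax(len2, 1e-300)))
    cl <- a + ab * t0
    out[i] <- sqrt(min(rowSums(sweep(cl, 2, p[i, ], "-")^2)))
  }
  out
}

contour_segments <- function(contour) {
  cl <- as_contour_list(contour)
  a <- list(); b <- list()
  for (cc in cl) {
    pp <- cc$points
    if (cc$closed) pp <- rbind(pp, pp[1, ])
    a[[length(a) + 1L]] <- pp[-nrow(pp), , drop = FALSE]
    b[[length(b) + 1L]] <- pp[-1, , drop = FALSE]
  }
  list(a = do.call(rbind, a), b = do.call(rbind, b))
}

#' Extract sub-polylines of a silhouette as an open multi-segment contour
#'
#' Emulates an investigator selecting only the reliable, well-defined
#' edges (e.g. corpus edges) of a projected silhouette: the requested
#' index ranges of the closed silhouette polygon become open segments.
#'
#' @param sil a closed `contour2d`.
#' @param segments list of integer index ranges `c(from, to)` into the
#'   silhouette points (inclusive; `to` may wrap past the end modulo n).
#' @return list of open `contour2d` segments.
#' @export
contour_from_silhouette <- function(sil, segments) {
  stopifnot(inherits(sil, "contour2d"), sil$closed)
  n <- nrow(sil$points)
  idx_of <- function(rg) {
    if (length(rg) != 2 || rg[1] < 1 || rg[1] > n || rg[2] < rg[1])
      stop("invalid index range")
    ((rg[1]:rg[2]) - 1L) %% n + 1L
  }
  all_idx <- lapply(segments, idx_of)
  flat <- unlist(all_idx)
  if (anyDuplicated(flat)) stop("overlapping index ranges")
  if (length(flat) == n)
    return(list(contour2d(sil$points, closed = TRUE, label = sil$label,
                          view = sil$view)))
  lapply(all_idx, function(ii)
    contour2d(sil$points[ii, , drop = FALSE], closed = FALSE,
              label = sil$label, view = sil$view))
}

#' Select contiguous arcs covering a fraction of a silhouette
#'
#' Convenience generator of partial target contours: `n_segments` arcs of
#' equal length totalling `fraction` of the silhouette points, at seeded
#' random angular positions.
#'
#' @param sil a closed `contour2d`.
#' @param fraction fraction of the silhouette to keep (0, 1].
#' @param n_segments number of arcs.
#' @param seed integer seed.
#' @return list of open `contour2d` segments (or the closed silhouette if
#'   `fraction >= 1`).
#' @export
partial_silhouette <- function(sil, fraction, n_segments = 2, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction >= 1) return(list(sil))
  n <- nrow(sil$points)
  len <- max(2L, floor(n * fraction / n_segments))
  gap <- floor(n / n_segments)
  start0 <- with_seed(seed, sample.int(n, 1))
  starts <- ((start0 + (seq_len(n_segments) - 1L) * gap) - 1L) %% n + 1L
  contour_from_silhouette(sil, lapply(starts, function(s) c(s, s + len - 1L)))
}

#' Gradient-attracted contour snapping
#'
#' Densifies the polyline through the control points (Catmull-Rom spline
#' or straight lines) and moves every sample along its local normal to the
#' position of maximum image gradient magnitude within `search_radius`. A
#' sample stays in place when no gradient above the threshold (a fraction
#' of the image's maximum gradient magnitude) exists in its window, so
#' straight lines and splines survive in flat image regions.
#'
#' @param image a `radiograph_image`.
#' @param control_points n x 2 matrix of detector mm coordinates (must be
#'   inside the image).
#' @param search_radius one-sided search window along the normal (mm).
#' @param densify_step sample spacing along the curve (mm).
#' @param mode `"spline"` (Catmull-Rom through the control points) or
#'   `"linear"`.
#' @param closed treat the control polygon as closed.
#' @param gradient_sigma Gaussian-derivative scale in pixels.
#' @param threshold_frac gradient acceptance threshold as a fraction of
#'   the image maximum.
#' @return A `contour2d` of snapped samples.
#' @export
snap_contour <- function(image, control_points, search_radius = 3,
                         densify_step = 0.5, mode = c("spline", "linear"),
                         closed = FALSE, gradient_sigma = 1,
                         threshold_frac = 0.1) {
  stopifnot(inherits(image, "radiograph_image"), search_radius > 0)
  mode <- match.arg(mode)
  cp <- as.matrix(control_points)
  ext <- image_extent(image)
  if (any(cp[, 1] < ext$umin | cp[, 1] > ext$umax |
          cp[, 2] < ext$vmin | cp[, 2] > ext$vmax))
    stop("control points outside the image")
  base <- if (mode == "spline" && nrow(cp) >= 3)
    catmull_rom(cp, densify_step, closed) else
    densify_contour(contour2d(cp, closed = closed), densify_step)$points
  g <- gradient_magnitude(image, gradient_sigma)
  gmax <- max(g)
  thr <- threshold_frac * gmax
  n <- nrow(base)
  tang <- base[pmin(n, seq_len(n) + 1), , drop = FALSE] -
          base[pmax(1, seq_len(n) - 1), , drop = FALSE]
  nr <- cbind(-tang[, 2], tang[, 1])
  nr <- nr / pmax(sqrt(rowSums(nr^2)), 1e-12)
  step <- image$pixel_spacing / 4
  offs <- seq(-search_radius, search_radius, by = step)
  snapped <- base
  for (i in seq_len(n)) {
    cand <- cbind(base[i, 1] + offs * nr[i, 1], base[i, 2] + offs * nr[i, 2])
    gv <- bilinear_sample(g, cand, image, ext)
    j <- which.max(gv)
    if (length(j) == 1 && is.finite(gv[j]) && gv[j] > thr)
      snapped[i, ] <- cand[j, ]
  }
  contour2d(snapped, closed = closed, view = image$view)
}

image_extent <- function(image) {
  ny <- nrow(image$pixels); nx <- ncol(image$pixels)
  half_u <- (nx - 1) / 2 * image$pixel_spacing
  half_v <- (ny - 1) / 2 * image$pixel_spacing
  list(umin = -half_u, umax = half_u, vmin = -half_v, vmax = half_v,
       nx = nx, ny = ny)
}

# Gaussian-derivative gradient magnitude (sigma in pixels).
gradient_magnitude <- function(image, sigma = 1) {
  sm <- gaussian_blur(image$pixels, sigma)
  ny <- nrow(sm); nx <- ncol(sm)
  gx <- (sm[, pmin(nx, seq_len(nx) + 1), drop = FALSE] -
         sm[, pmax(1, seq_len(nx) - 1), drop = FALSE]) / 2
  gy <- (sm[pmin(ny, seq_len(ny) + 1), , drop = FALSE] -
         sm[pmax(1, seq_len(ny) - 1), , drop = FALSE]) / 2
  sqrt(gx^2 + gy^2) / image$pixel_spacing
}

# Bilinear sampling of a pixel matrix at detector mm coordinates.
bilinear_sample <- function(mat, uv, image, ext) {
  col <- (uv[, 1] - ext$umin) / image$pixel_spacing + 1
  row <- (ext$vmax - uv[, 2]) / image$pixel_spacing + 1
  col <- pmin(pmax(col, 1), ext$nx)
  row <- pmin(pmax(row, 1), ext$ny)
  c0 <- pmin(floor(col), ext$nx - 1); r0 <- pmin(floor(row), ext$ny - 1)
  fc <- col - c0; fr <- row - r0
  idx <- function(r, c) mat[cbind(r, c)]
  idx(r0, c0) * (1 - fr) * (1 - fc) + idx(r0 + 1, c0) * fr * (1 - fc) +
    idx(r0, c0 + 1) * (1 - fr) * fc + idx(r0 + 1, c0 + 1) * fr * fc
}

# Uniform-parameter Catmull-Rom spline through control points.
catmull_rom <- function(cp, step, closed = FALSE) {
  n <- nrow(cp)
  pts <- if (closed) rbind(cp[n, ], cp, cp[1, ], cp[2, ]) else
    rbind(cp[1, ], cp, cp[n, ])
  out <- list()
  nseg <- nrow(pts) - 3
  for (s in seq_len(nseg)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1, ]; p2 <- pts[s + 2, ]; p3 <- pts[s + 3, ]
    L <- sqrt(sum((p2 - p1)^2))
    m <- max(2L, ceiling(L / step) + 1L)
    t0 <- seq(0, 1, length.out = m)
    if (s < nseg) t0 <- t0[-m]
    tt2 <- t0 * t0; tt3 <- tt2 * t0
    b <- cbind(-0.5 * tt3 + tt2 - 0.5 * t0,
               1.5 * tt3 - 2.5 * tt2 + 1,
               -1.5 * tt3 + 2 * tt2 + 0.5 * t0,
               0.5 * tt3 - 0.5 * tt2)
    out[[s]] <- b %*% rbind(p0, p1, p2, p3)
  }
  do.call(rbind, out)
}

#' Contour JSON serialization
#'
#' Contours (single or multi-segment) are stored as a JSON list of
#' objects with `label`, `view`, `closed` and `points` (mm).
#'
#' @param contours a `contour2d` or list of them.
#' @param path file path.
#' @export
write_contours_json <- function(contours, path) {
  cl <- as_contour_list(contours)
  jsonlite::write_json(lapply(cl, function(cc) list(
    label = cc$label, view = cc$view, closed = cc$closed,
    points = cc$points)), path, digits = NA, auto_unbox = TRUE,
    null = "null")
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i) {
    contour2d(obj$points[[i]], closed = obj$closed[i],
              label = if (is.na(obj$label[i])) NULL else obj$label[i],
              view = if (is.na(obj$view[i])) NULL else obj$view[i])
  })
}
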