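#' Midsagittal plane of a spine model
#'
#' The sagittal mid-plane between the left and right vertebral margins:
#' its normal is the world left-right (x) axis, its offset the midpoint of
#' the extreme left and right vertex coordinates over all vertebral bodies.
#'
#' @param spine a `spine_model`.
#' @return list with `origin` and `normal` (world mm).
#' @export
midsagittal_plane <- function(spine) {
  if (length(spine$vertebrae) == 0) stop("empty spine model")
  xs <- unlist(lapply(spine$vertebrae, function(v) {
    sel <- if (is.null(v$mesh$regions)) rep(TRUE, nrow(v$mesh$faces))
           else v$mesh$regions == "body"
    idx <- unique(as.vector(v$mesh$faces[sel, , drop = FALSE]))
    apply_transform(v$pose, v$mesh$vertices[idx, , drop = FALSE])[, 1]
  }))
  list(origin = c((min(xs) + max(xs)) / 2, 0, 0), normal = c(1, 0, 0))
}

#' Rasterized midsagittal section image
#'
#' Cross-section of the full registered geometry by a (near-)sagittal
#' plane, rasterized as a filled binary image; the analog of the
#' postregistrational midsagittal section measured on radiographs.
#'
#' @param spine a `spine_model`.
#' @param plane list with `origin`, `normal` (normal within 5 degrees of
#'   the left-right axis); default the [midsagittal_plane()].
#' @param pixel_spacing raster step (mm).
#' @return An object of class `section_image`: `pixels` (row 1 most
#'   cranial), in-plane axes (`ay` = anterior, `az` = cranial), extent and
#'   plane metadata.
#' @export
section_image <- function(spine, plane = midsagittal_plane(spine),
                          pixel_spacing = 0.5) {
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  if (.rad2deg(acos(min(1, abs(nrm[1])))) > 5)
    stop("section plane normal must be within 5 degrees of the x axis")
  ay <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
  ay <- ay / sqrt(sum(ay^2))
  az <- cross3(nrm, ay)
  bb <- do.call(rbind, lapply(vertebra_labels(), function(l)
    mesh_bbox(posed_mesh(spine, l))))
  ylim <- range(bb[, 2]) + c(-2, 2)
  zlim <- range(bb[, 3]) + c(-2, 2)
  gy <- seq(ylim[1], ylim[2], by = pixel_spacing)
  gz <- seq(zlim[1], zlim[2], by = pixel_spacing)
  g <- as.matrix(expand.grid(y = gy, z = gz))
  pts <- cbind(plane$origin[1] + g[, 1] * ay[1] + g[, 2] * az[1],
               plane$origin[2] + g[, 1] * ay[2] + g[, 2] * az[2],
               plane$origin[3] + g[, 1] * ay[3] + g[, 2] * az[3])
  inside <- rep(FALSE, nrow(pts))
  hit_any <- FALSE
  for (l in vertebra_labels()) {
    wm <- posed_mesh(spine, l)
    bbm <- mesh_bbox(wm)
    cand <- which(pts[, 1] >= bbm[1, 1] & pts[, 1] <= bbm[2, 1] &
                  pts[, 2] >= bbm[1, 2] & pts[, 2] <= bbm[2, 2] &
                  pts[, 3] >= bbm[1, 3] & pts[, 3] <= bbm[2, 3])
    if (length(cand) == 0) next
    comp <- mesh_components(wm)
    jit <- matrix(rep(c(1.3e-5, 2.7e-5, 3.1e-5), each = length(cand)),
                  ncol = 3)
    ins <- cpp_points_in_mesh(pts[cand, , drop = FALSE] + jit,
                              wm$vertices, wm$faces, comp, max(comp))
    inside[cand[ins]] <- TRUE
    hit_any <- hit_any || any(ins)
  }
  if (!hit_any) stop("section plane does not intersect the geometry")
  mask <- matrix(inside, nrow = length(gy))  # [iy, iz]
  pixels <- t(mask)[length(gz):1, , drop = FALSE] * 1.0
  structure(list(pixels = pixels, plane = list(origin = plane$origin,
                                               normal = nrm),
                 pixel_spacing = pixel_spacing,
                 y_range = range(gy), z_range = range(gz)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px @ %.2f mm, %.0f mm^2 filled\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_spacing,
              sum(x$pixels) * x$pixel_spacing^2))
  invisible(x)
}

#' @export
plot.section_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, nrow(x$pixels):1, drop = FALSE],
                  col = c("black", "white"), asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' Write a section image plus plane metadata
#'
#' PNG raster plus a JSON sidecar (`<path>.json`) with the plane origin,
#' normal and pixel spacing.
#'
#' @param section a `section_image`.
#' @param path output PNG path.
#' @export
write_section_png <- function(section, path) {
  png::writePNG(section$pixels, path)
  jsonlite::write_json(list(origin = section$plane$origin,
                            normal = section$plane$normal,
                            pixel_spacing = section$pixel_spacing,
                            y_range = section$y_range,
                            z_range = section$z_range),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

# In-plane (y = anterior, z = cranial) endplate segments of one vertebra:
# intersection of its body-region faces with the plane, keeping only faces
# whose world normal is within 30 degrees of the vertebra's +/- cranial axis.
section_endplate_points <- function(vert, plane, which) {
  mesh <- vert$mesh
  sel <- if (is.null(mesh$regions)) rep(TRUE, nrow(mesh$faces))
         else mesh$regions == "body"
  wn <- face_normals(apply_transform(vert$pose, mesh))
  axis_cr <- as.numeric(vert$pose$R %*% c(0, 0, 1))
  s <- if (which == "cranial") 1 else -1
  sel <- sel & (as.numeric(wn %*% axis_cr) * s > cos(.deg2rad(30)))
  if (!any(sel)) stop("endplate not found in section (", which, ")")
  wv <- apply_transform(vert$pose, mesh$vertices)
  d <- as.numeric(sweep(wv, 2, plane$origin, "-") %*% plane$normal)
  f <- mesh$faces[sel, , drop = FALSE]
  pts <- list()
  for (k in seq_len(nrow(f))) {
    vi <- f[k, ]
    dv <- d[vi]
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      d1 <- dv[e[1]]; d2 <- dv[e[2]]
      if ((d1 <= 0 && d2 > 0) || (d1 > 0 && d2 <= 0)) {
        t0 <- d1 / (d1 - d2)
        pts[[length(pts) + 1L]] <- wv[vi[e[1]], ] +
          t0 * (wv[vi[e[2]], ] - wv[vi[e[1]], ])
      }
    }
  }
  if (length(pts) < 2) return(NULL)
  p <- do.call(rbind, pts)
  cbind(y = p[, 2], z = p[, 3])
}

# Fit a line through 2D (y, z) points; returns its sagittal inclination in
# degrees vs the transverse plane, anterior direction positive-up.
fit_line_angle <- function(p) {
  if (nrow(p) < 2) stop("too few points for endplate line fit")
  cv <- stats::cov(p)
  e <- eigen(cv, symmetric = TRUE)
  d <- e$vectors[, 1]
  if (d[1] < 0) d <- -d  # orient anterior
  .rad2deg(atan2(d[2], d[1]))
}

#' Endplate line of one vertebra in the sagittal plane
#'
#' Least-squares line through the endplate point set of the requested
#' vertebra, reported as the signed inclination (degrees) of the endplate
#' versus the world transverse plane in the sagittal (y-z) projection.
#' Two routes are available: `"mesh"` fits the 3D endplate vertex set
#' (body-region faces whose outward normals lie within 30 degrees of the
#' vertebra's cranio-caudal axis) projected into the sagittal plane;
#' `"section"` fits the intersection of those faces with the midsagittal
#' plane, i.e. the endplate edge as seen in the section image.
#'
#' @param spine a `spine_model`.
#' @param label vertebral label.
#' @param which `"cranial"` or `"caudal"`.
#' @param route `"mesh"` or `"section"`.
#' @param plane section plane (for the section route).
#' @return inclination angle in degrees.
#' @export
endplate_line <- function(spine, label, which = c("cranial", "caudal"),
                          route = c("mesh", "section"),
                          plane = midsagittal_plane(spine)) {
  which <- match.arg(which)
  route <- match.arg(route)
  vert <- spine$vertebrae[[label]]
  if (is.null(vert)) stop("no vertebra labelled ", label)
  if (route == "mesh") {
    vl <- tryCatch(endplate_vertices(vert$mesh, which),
                   error = function(e) stop(label, ": ",
                                            conditionMessage(e),
                                            call. = FALSE))
    p <- apply_transform(vert$pose, vl)[, c(2, 3), drop = FALSE]
  } else {
    p <- section_endplate_points(vert, plane, which)
    if (is.null(p)) stop(label, ": endplate does not cross the section plane")
  }
  fit_line_angle(p)
}

#' Intersegmental and lumbar lordosis angles
#'
#' Measures the five intersegmental angles (signed angle between the
#' caudal endplate line of the upper and the cranial endplate line of the
#' lower vertebra of each segment) and the lumbar lordosis LL (cranial
#' endplate of L1 versus cranial endplate of S1), lordotic (extension)
#' angles positive. The `"section"` route measures on midsagittal-section
#' endplate edges, the analog of reading the section image; the `"mesh"`
#' route fits the 3D endplate patches directly.
#'
#' @param spine a `spine_model` (e.g. ground-truth standing pose or a
#'   registered model via [registered_spine()]).
#' @param route `"section"` or `"mesh"`.
#' @param plane section plane for the section route.
#' @return An object of class `angle_set`: `intersegmental` (named,
#'   degrees), `LL` (degrees).
#' @export
compute_angles <- function(spine, route = c("section", "mesh"),
                           plane = midsagittal_plane(spine)) {
  route <- match.arg(route)
  labs <- vertebra_labels()
  cranial <- vapply(labs, function(l)
    endplate_line(spine, l, "cranial", route, plane), numeric(1))
  caudal <- vapply(labs[1:5], function(l)
    endplate_line(spine, l, "caudal", route, plane), numeric(1))
  inter <- stats::setNames(numeric(5), segment_labels())
  for (i in 1:5) inter[i] <- caudal[labs[i]] - cranial[labs[i + 1]]
  angle_set(inter, cranial["L1"] - cranial["S"])
}

#' @rdname compute_angles
#' @param intersegmental named length-5 vector of segment angles (deg).
#' @param LL lumbar lordosis (deg).
#' @export
angle_set <- function(intersegmental, LL) {
  structure(list(
    intersegmental = stats::setNames(as.numeric(intersegmental),
                                     segment_labels()),
    LL = as.numeric(LL)), class = "angle_set")
}

#' @export
print.angle_set <- function(x, ...) {
  cat("<angle_set> (deg, lordotic positive)\n")
  print(round(c(x$intersegmental, LL = x$LL), 2))
  invisible(x)
}

#' @export
as.data.frame.angle_set <- function(x, ...) {
  as.data.frame(as.list(c(x$intersegmental, LL = x$LL)))
}

#' Elementwise absolute angle differences
#'
#' @param a,b `angle_set` objects with the same sign convention.
#' @return An `angle_set` of absolute differences (degrees).
#' @export
angle_abs_diff <- function(a, b) {
  angle_set(abs(a$intersegmental - b$intersegmental), abs(a$LL - b$LL))
}

#' Spine model with registered poses substituted
#'
#' @param spine the source `spine_model` (supplies the local meshes the
#'   registration started from).
#' @param results named list of `registration_result` (or of
#'   `rigid_transform`) per label.
#' @return A `spine_model` whose poses are the registered ones.
#' @export
registered_spine <- function(spine, results) {
  for (l in vertebra_labels()) {
    r <- results[[l]]
    if (is.null(r)) stop("missing registration result for ", l)
    pose <- if (inherits(r, "registration_result")) r$final_pose else r
    spine$vertebrae[[l]]$pose <- pose
  }
  spine
}
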