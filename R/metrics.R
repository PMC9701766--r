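#' Voxelize a mesh on an isotropic grid
#'
#' Occupancy mask of voxels whose centers lie inside the posed mesh. The
#' default 0.6 mm voxel mirrors the CT reconstruction grid. Meshes made of
#' several closed components (the synthetic vertebrae) are handled by
#' per-component inside tests.
#'
#' @param mesh a `triangle_mesh` (must be watertight).
#' @param pose `rigid_transform` applied before voxelization.
#' @param voxel_size isotropic voxel edge (mm).
#' @param bounds optional 2 x 3 matrix (min row, max row) fixing the grid;
#'   use a shared bounds for masks that will be compared.
#' @return An object of class `voxel_mask`: logical 3D `occupancy`,
#'   `voxel_size`, `origin` (center of voxel [1,1,1]).
#' @export
voxelize <- function(mesh, pose = transform_identity(), voxel_size = 0.6,
                     bounds = NULL) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (!is_watertight(mesh))
    stop("mesh is not watertight; voxel occupancy is undefined")
  wm <- apply_transform(pose, mesh)
  if (is.null(bounds)) {
    bb <- mesh_bbox(wm)
    bounds <- rbind(bb[1, ] - voxel_size, bb[2, ] + voxel_size)
  }
  n <- pmax(1L, as.integer(ceiling((bounds[2, ] - bounds[1, ]) / voxel_size)))
  origin <- bounds[1, ] + voxel_size / 2
  comp <- mesh_components(wm)
  # nudge the grid off exact vertex/edge alignments for robust ray parity
  ins <- cpp_voxelize_grid(wm$vertices, wm$faces, comp, max(comp),
                           origin - c(1.3e-5, 2.7e-5, 3.1e-5), voxel_size, n)
  structure(list(occupancy = array(ins, dim = n), voxel_size = voxel_size,
                 origin = origin), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels @ %.2f mm, %d occupied (%.1f mm^3)\n",
              paste(dim(x$occupancy), collapse = " x "), x$voxel_size,
              sum(x$occupancy), sum(x$occupancy) * x$voxel_size^3))
  invisible(x)
}

#' Dice similarity index of two voxel masks
#'
#' `DSI = 2|X n Y| / (|X| + |Y|)` on the occupied-voxel sets; 1 means
#' identical sets. Both masks must live on the same grid.
#'
#' @param x,y `voxel_mask` objects on a common grid.
#' @return Dice index in [0, 1].
#' @export
dice <- function(x, y) {
  if (x$voxel_size != y$voxel_size ||
      !isTRUE(all.equal(x$origin, y$origin, tolerance = 1e-9)) ||
      !identical(dim(x$occupancy), dim(y$occupancy)))
    stop("voxel grids do not match (size, origin and dimensions must agree)")
  nx <- sum(x$occupancy); ny <- sum(y$occupancy)
  if (nx + ny == 0) stop("both masks are empty; Dice is undefined")
  2 * sum(x$occupancy & y$occupancy) / (nx + ny)
}

#' Voxelize two posed meshes on a shared grid
#'
#' Convenience wrapper computing the joint bounding box so the two masks
#' are directly comparable with [dice()].
#'
#' @param mesh1,mesh2 `triangle_mesh` objects.
#' @param pose1,pose2 poses.
#' @param voxel_size voxel edge (mm).
#' @return list of two `voxel_mask` objects.
#' @export
voxelize_pair <- function(mesh1, pose1, mesh2, pose2, voxel_size = 0.6) {
  b1 <- mesh_bbox(apply_transform(pose1, mesh1))
  b2 <- mesh_bbox(apply_transform(pose2, mesh2))
  bounds <- rbind(pmin(b1[1, ], b2[1, ]) - voxel_size,
                  pmax(b1[2, ], b2[2, ]) + voxel_size)
  list(voxelize(mesh1, pose1, voxel_size, bounds),
       voxelize(mesh2, pose2, voxel_size, bounds))
}

#' Metro-style mean surface distance
#'
#' One-sided, area-weighted mean of point-to-surface distances,
#' `E_m(S1, S2) = (1/|S1|) * integral over S1 of e(p, S2) ds`, estimated
#' by stratified area-proportional sampling on `s1` with exact
#' point-to-triangle distances to `s2`. The symmetric variant reports the
#' larger of the two one-sided values.
#'
#' @param s1,s2 `triangle_mesh` objects (world frame).
#' @param samples_per_mm2 sampling density on `s1`.
#' @param symmetric report `max(E_m(s1,s2), E_m(s2,s1))`.
#' @param seed integer seed for the surface sampling.
#' @return mean distance (mm).
#' @export
mean_surface_distance <- function(s1, s2, samples_per_mm2 = 10,
                                  symmetric = FALSE, seed = NULL) {
  one_sided <- function(a, b, sd_seed) {
    if (mesh_area(a) <= 0 || mesh_area(b) <= 0)
      stop("zero-area surface")
    sm <- sample_mesh_points(a, samples_per_mm2, seed = sd_seed)
    d <- cpp_point_mesh_distance(sm$points, b$vertices, b$faces)
    sum(d * sm$weights) / sum(sm$weights)
  }
  if (symmetric)
    max(one_sided(s1, s2, seed), one_sided(s2, s1, if (is.null(seed)) NULL
                                           else seed + 1L))
  else one_sided(s1, s2, seed)
}

#' Symmetrized maximum (Hausdorff) surface distance
#'
#' Supremum over sampled surface points (vertices included) of the
#' distance to the other surface, symmetrized over the two directions.
#'
#' @inheritParams mean_surface_distance
#' @return Hausdorff distance estimate (mm).
#' @export
hausdorff_max <- function(s1, s2, samples_per_mm2 = 10, seed = NULL) {
  one_sided <- function(a, b, sd_seed) {
    if (mesh_area(a) <= 0 || mesh_area(b) <= 0)
      stop("zero-area surface")
    sm <- sample_mesh_points(a, samples_per_mm2, seed = sd_seed)
    p <- rbind(sm$points, a$vertices)
    max(cpp_point_mesh_distance(p, b$vertices, b$faces))
  }
  max(one_sided(s1, s2, seed),
      one_sided(s2, s1, if (is.null(seed)) NULL else seed + 1L))
}

#' Intraclass correlation coefficient (two-way, absolute agreement)
#'
#' Two-way mixed-effects, absolute-agreement ICC with F-based 95%
#' confidence interval: `single` is the single-measurement form ICC(A,1)
#' (intra-rater use), `mean_k` the mean-of-k-raters form ICC(A,k)
#' (inter-rater use with k = 2). Computed from the two-way ANOVA mean
#' squares (rows = cases, columns = raters/timepoints).
#'
#' @param ratings n x k numeric matrix, one row per case, one column per
#'   rater/timepoint; no missing values, n >= 5.
#' @param variant `"single"` (ICC(A,1)) or `"mean_k"` (ICC(A,k)).
#' @param conf_level confidence level (0.95 to match common practice).
#' @return An object of class `icc_estimate`: `estimate`, `lower`,
#'   `upper`, `variant`, `n`, `k`.
#' @export
icc <- function(ratings, variant = c("single", "mean_k"),
                conf_level = 0.95) {
  variant <- match.arg(variant)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing ratings are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("need at least 5 cases")
  if (k < 2) stop("need at least 2 raters/timepoints")
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings); gm <- mean(ratings)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (ssr <= 1e-12 * max(1, gm^2))
    stop("zero between-case variance; ICC undefined")
  est1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- (k * est1) / (n * (1 - est1))
  b <- 1 + (k * est1 * (n - 1)) / (n * (1 - est1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)  # Spearman-Brown step-up
  out <- if (variant == "single") c(est1, lo1, up1)
         else c(sb(est1), sb(lo1), sb(up1))
  structure(list(estimate = out[1], lower = out[2], upper = out[3],
                 variant = variant, n = n, k = k,
                 conf_level = conf_level), class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC(A,%s) = %.3f, %d%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              if (x$variant == "single") "1" else "k", x$estimate,
              round(100 * x$conf_level), x$lower, x$upper, x$n, x$k))
  invisible(x)
}
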