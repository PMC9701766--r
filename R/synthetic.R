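#' Parametric vertebra shape
#'
#' Shape parameters of a simplified synthetic vertebra: a rounded-box
#' vertebral body (superelliptic cross-section, planar cranial and caudal
#' endplates whose dihedral is the wedge angle) plus box-shaped posterior
#' elements (arch, left/right transverse processes, spinous process). The
#' registration method only relies on projected edges of the body and the
#' proximal process regions, so anatomical realism beyond that is not a
#' goal. A small seeded low-order Fourier perturbation of the body
#' cross-section makes each case geometrically distinct while preserving
#' mirror symmetry about the local sagittal midplane and planar endplates.
#'
#' Local frame: origin at the body center, +x patient-left, +y anterior,
#' +z cranial; all lengths in mm, wedge angle in degrees (positive wedge =
#' taller anteriorly, i.e. lordotic).
#'
#' @param body_width,body_depth,body_height body extents (mm).
#' @param wedge_angle dihedral between cranial and caudal endplates (deg),
#'   `|wedge_angle| < 30`.
#' @param process_transverse,process_spinous process lengths (mm).
#' @param jitter relative amplitude of the seeded cross-section
#'   perturbation.
#' @param caudal_block sacrum only: attach a posteriorly angled caudal
#'   block below the body, emulating the sacral curvature whose anterior
#'   ridge (the promontory edge) is a key sagittal contouring landmark.
#' @param seed integer seed making the shape deterministic.
#' @return An object of class `vertebra_shape_params`.
#' @export
vertebra_shape_params <- function(body_width = 46, body_depth = 32,
                                  body_height = 28, wedge_angle = 2,
                                  process_transverse = 22,
                                  process_spinous = 28,
                                  jitter = 0.01, caudal_block = FALSE,
                                  seed = 1L) {
  if (any(c(body_width, body_depth, body_height,
            process_transverse, process_spinous) <= 0))
    stop("all shape dimensions must be positive")
  if (abs(wedge_angle) >= 30) stop("|wedge_angle| must be < 30 degrees")
  structure(list(body_width = body_width, body_depth = body_depth,
                 body_height = body_height, wedge_angle = wedge_angle,
                 process_transverse = process_transverse,
                 process_spinous = process_spinous,
                 jitter = jitter, caudal_block = isTRUE(caudal_block),
                 seed = as.integer(seed)),
            class = "vertebra_shape_params")
}

#' Default per-level shape parameters
#'
#' Typical adult lumbar dimensions; the sacrum (`S`) is represented by its
#' S1 body block with wide transverse elements (alae) and a larger wedge.
#'
#' @param label vertebral label.
#' @param seed integer seed (per-label seeds are derived from it).
#' @return A `vertebra_shape_params`.
#' @export
default_shape_params <- function(label, seed = 1L) {
  label <- match.arg(label, vertebra_labels())
  tab <- list(
    L1 = list(42, 30, 27, 1, 22, 26),
    L2 = list(44, 31, 28, 1, 23, 28),
    L3 = list(46, 32, 29, 2, 24, 28),
    L4 = list(48, 33, 28, 3, 24, 26),
    L5 = list(50, 34, 27, 7, 25, 22),
    S  = list(55, 36, 34, 14, 30, 12))[[label]]
  vertebra_shape_params(tab[[1]], tab[[2]], tab[[3]], tab[[4]], tab[[5]],
                        tab[[6]], caudal_block = label == "S",
                        seed = seed * 101L + match(label, vertebra_labels()))
}

#' @rdname default_shape_params
#' @export
default_spine_shapes <- function(seed = 1L) {
  stats::setNames(lapply(vertebra_labels(), default_shape_params, seed = seed),
                  vertebra_labels())
}

#' Generate a synthetic vertebra mesh
#'
#' @param params a `vertebra_shape_params`.
#' @param label optional vertebral label to attach.
#' @param n_ring number of points around the body cross-section.
#' @return A watertight, mirror-symmetric `triangle_mesh` whose faces carry
#'   region tags (`body`, `arch`, `transverse_left`, `transverse_right`,
#'   `spinous`).
#' @export
make_vertebra <- function(params, label = NULL, n_ring = 40) {
  stopifnot(inherits(params, "vertebra_shape_params"))
  W <- params$body_width; D <- params$body_depth; h <- params$body_height
  wtan <- tan(.deg2rad(params$wedge_angle / 2))
  theta <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  p <- 4  # superellipse exponent: rounded box
  sx <- sign(cos(theta)) * abs(cos(theta))^(2 / p)
  sy <- sign(sin(theta)) * abs(sin(theta))^(2 / p)
  # mirror-symmetric radial perturbation: even cosine series in (theta - pi/2)
  g <- with_seed(params$seed, {
    a <- stats::runif(4, -1, 1)
    1 + params$jitter * as.numeric(cos(outer(theta - pi / 2, 1:4)) %*% a) / 2
  })
  x <- (W / 2) * sx * g
  y <- (D / 2) * sy * g
  zb <- -h / 2 - wtan * y
  zt <- h / 2 + wtan * y
  v <- rbind(cbind(x, y, zb), cbind(x, y, zt),
             c(0, 0, -h / 2), c(0, 0, h / 2))
  ib <- seq_len(n_ring); it <- n_ring + ib
  cb <- 2L * n_ring + 1L; ct <- 2L * n_ring + 2L
  nxt <- c(ib[-1], ib[1])
  f <- rbind(
    cbind(ib, it[nxt], it),                  # side quads (two fans of tris)
    cbind(ib, nxt, it[nxt]),
    cbind(cb, nxt, ib),                      # caudal cap (outward -z)
    cbind(ct, it, it[nxt]))                  # cranial cap (outward +z)
  body <- triangle_mesh(v, f, regions = rep("body", nrow(f)))
  arch <- mesh_box(c(0.6 * W, 10, 0.5 * h), c(0, -D / 2 - 3, 0),
                   region = "arch")
  tpl <- mesh_box(c(params$process_transverse, 8, 8),
                  c(0.25 * W + params$process_transverse / 2, -D / 2, 0),
                  region = "transverse_left")
  tpr <- mesh_box(c(params$process_transverse, 8, 8),
                  c(-0.25 * W - params$process_transverse / 2, -D / 2, 0),
                  region = "transverse_right")
  sp <- mesh_box(c(8, params$process_spinous, 0.4 * h),
                 c(0, -D / 2 - 4 - params$process_spinous / 2, 0),
                 region = "spinous")
  parts <- list(body, arch, tpl, tpr, sp)
  if (params$caudal_block) {
    # posteriorly angled caudal sacrum; its anterior-superior ridge plays
    # the role of the promontory edge in the sagittal silhouette
    blk <- mesh_box(c(0.6 * W, 0.8 * D, 36), c(0, 0, 0),
                    region = "sacrum_caudal")
    blk <- apply_transform(
      rigid_transform(rot_x(-30), c(0, -0.15 * D, -h / 2 - 10)), blk)
    parts <- c(parts, list(blk))
  }
  m <- merge_meshes(parts, label = label)
  ensure_outward(m)
}

# Concatenate meshes into one (disjoint closed components), keeping regions.
merge_meshes <- function(meshes, label = NULL) {
  off <- 0L
  v <- list(); f <- list(); r <- list()
  for (m in meshes) {
    v[[length(v) + 1L]] <- m$vertices
    f[[length(f) + 1L]] <- m$faces + off
    r[[length(r) + 1L]] <- if (is.null(m$regions))
      rep(NA_character_, nrow(m$faces)) else m$regions
    off <- off + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, v), do.call(rbind, f), label = label,
                regions = do.call(c, r))
}

#' Sagittal alignment plan
#'
#' The five intersegmental angles (degrees; between the caudal endplate of
#' the upper and the cranial endplate of the lower vertebra of each
#' segment) and disc heights (mm) of a lumbar spine, lordotic (extension)
#' angles positive.
#'
#' @param intersegmental_angles length-5 numeric, order
#'   `L1-L2, L2-L3, L3-L4, L4-L5, L5-S1` (deg).
#' @param disc_heights length-5 or scalar disc heights (mm).
#' @return An object of class `sagittal_plan`.
#' @export
sagittal_plan <- function(intersegmental_angles, disc_heights = 10) {
  stopifnot(length(intersegmental_angles) == 5L)
  disc_heights <- rep_len(disc_heights, 5L)
  structure(list(
    intersegmental_angles = stats::setNames(as.numeric(intersegmental_angles),
                                            segment_labels()),
    disc_heights = as.numeric(disc_heights)), class = "sagittal_plan")
}

#' @rdname sagittal_plan
#' @export
segment_labels <- function() c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1")

#' Default supine and standing plans
#'
#' Standing lumbar lordosis 50.6 deg and supine 45.0 deg with the default
#' shapes (difference 5.6 deg, the supine-to-standing effect size the
#' generator emulates).
#'
#' @param posture `"standing"` or `"supine"`.
#' @return A `sagittal_plan`.
#' @export
default_sagittal_plan <- function(posture = c("standing", "supine")) {
  posture <- match.arg(posture)
  if (posture == "standing") sagittal_plan(c(2, 5, 7, 10, 12.6))
  else sagittal_plan(c(1.4, 4, 6, 9, 10.6))
}

#' Lumbar lordosis implied by a plan
#'
#' The lordosis between the cranial endplate of L1 and the cranial
#' endplate of S1 equals the sum of the five intersegmental (disc) angles
#' plus the wedge angles of the five lumbar vertebral bodies.
#'
#' @param plan a `sagittal_plan`.
#' @param shapes named list of `vertebra_shape_params` (`L1`..`S`).
#' @return lordosis in degrees.
#' @export
plan_ll <- function(plan, shapes) {
  w <- vapply(shapes[c("L1", "L2", "L3", "L4", "L5")],
              function(s) s$wedge_angle, numeric(1))
  sum(plan$intersegmental_angles) + sum(w)
}

#' Assemble a spine model from shapes and a sagittal plan
#'
#' Vertebrae are stacked caudal to cranial with pure left-right (x) axis
#' intersegmental rotations; disc heights are translation gaps along the
#' local inter-vertebral axis. The sacrum is placed at the origin with its
#' body axis vertical, so the world frame is sacrum-aligned.
#'
#' @param shapes named list of `vertebra_shape_params` for `L1`..`L5`, `S`
#'   (a single seed via [default_spine_shapes()] is the usual source).
#' @param plan a `sagittal_plan`.
#' @param overlap_tol adjacent vertebrae may interpenetrate at most this
#'   much (mm) along the segment axis before an error is thrown.
#' @return An object of class `spine_model`: named list of vertebrae, each
#'   with `mesh` (local frame) and `pose` (a `rigid_transform` local ->
#'   world).
#' @export
assemble_spine <- function(shapes, plan, overlap_tol = 0.2) {
  stopifnot(inherits(plan, "sagittal_plan"))
  labs <- vertebra_labels()
  if (!all(labs %in% names(shapes)))
    stop("shapes must be named and contain all of ", paste(labs, collapse = ", "))
  meshes <- lapply(labs, function(l) make_vertebra(shapes[[l]], label = l))
  names(meshes) <- labs
  wedge <- vapply(labs, function(l) shapes[[l]]$wedge_angle, numeric(1))
  hgt <- vapply(labs, function(l) shapes[[l]]$body_height, numeric(1))
  a <- plan$intersegmental_angles  # L1L2 .. L5S1
  phi <- numeric(6); names(phi) <- labs
  phi["S"] <- 0
  for (i in 5:1) {  # segment i joins labs[i] (upper) and labs[i+1] (lower)
    up <- labs[i]; lo <- labs[i + 1]
    phi[up] <- phi[lo] + a[i] + wedge[up] / 2 + wedge[lo] / 2
  }
  poses <- vector("list", 6); names(poses) <- labs
  poses[["S"]] <- rigid_transform(rot_x(phi["S"]), c(0, 0, 0))
  anchor <- as.numeric(poses[["S"]]$R %*% c(0, 0, hgt["S"] / 2))
  for (i in 5:1) {
    up <- labs[i]; lo <- labs[i + 1]
    Ru <- rot_x(phi[up])
    mid <- rot_x((phi[up] + phi[lo]) / 2)
    tu <- anchor + as.numeric(mid %*% c(0, 0, plan$disc_heights[i])) -
      as.numeric(Ru %*% c(0, 0, -hgt[up] / 2))
    poses[[up]] <- rigid_transform(Ru, tu)
    anchor <- tu + as.numeric(Ru %*% c(0, 0, hgt[up] / 2))
  }
  spine <- structure(
    list(vertebrae = stats::setNames(lapply(labs, function(l)
      list(mesh = meshes[[l]], pose = poses[[l]])), labs),
      plan = plan),
    class = "spine_model")
  check_no_interpenetration(spine, phi, overlap_tol)
  spine
}

# Adjacent-pair overlap check: project the facing endplate rings onto the
# mid-segment axis and require a non-negative gap (within tolerance).
check_no_interpenetration <- function(spine, phi, tol) {
  labs <- vertebra_labels()
  for (i in 1:5) {
    up <- spine$vertebrae[[labs[i]]]; lo <- spine$vertebrae[[labs[i + 1]]]
    axis_mid <- as.numeric(rot_x((phi[labs[i]] + phi[labs[i + 1]]) / 2) %*%
                             c(0, 0, 1))
    vu <- endplate_vertices(up$mesh, "caudal")
    vl <- endplate_vertices(lo$mesh, "cranial")
    pu <- apply_transform(up$pose, vu) %*% axis_mid
    pl <- apply_transform(lo$pose, vl) %*% axis_mid
    if (min(pu) - max(pl) < -tol)
      stop(sprintf("vertebrae %s and %s interpenetrate by %.2f mm",
                   labs[i], labs[i + 1], max(pl) - min(pu)))
  }
  invisible(TRUE)
}

# Local-frame vertices of the cranial or caudal endplate of a vertebra:
# body-region faces whose outward normal is within 30 deg of +/- local z.
endplate_vertices <- function(mesh, which = c("cranial", "caudal")) {
  which <- match.arg(which)
  n <- face_normals(mesh)
  sel <- if (is.null(mesh$regions)) rep(TRUE, nrow(mesh$faces))
         else mesh$regions == "body"
  s <- if (which == "cranial") 1 else -1
  sel <- sel & (s * n[, 3] > cos(.deg2rad(30)))
  if (!any(sel)) stop("endplate not found (", which, ")")
  idx <- unique(as.vector(mesh$faces[sel, , drop = FALSE]))
  mesh$vertices[idx, , drop = FALSE]
}

#' @export
print.spine_model <- function(x, ...) {
  cat("<spine_model> L1..L5, S;",
      sum(vapply(x$vertebrae, function(v) nrow(v$mesh$faces), numeric(1))),
      "faces total\n")
  invisible(x)
}

#' World-frame (posed) mesh of one vertebra
#' @param spine a `spine_model`.
#' @param label vertebral label.
#' @return A `triangle_mesh` in world coordinates.
#' @export
posed_mesh <- function(spine, label) {
  v <- spine$vertebrae[[label]]
  if (is.null(v)) stop("no vertebra labelled ", label)
  apply_transform(v$pose, v$mesh)
}

#' Build a supine/standing pose pair with ground-truth transforms
#'
#' Both models share identical local meshes (same shape seeds); the
#' returned per-vertebra transforms map supine world poses exactly onto
#' standing world poses.
#'
#' @param shapes named list of `vertebra_shape_params`.
#' @param supine_plan,standing_plan `sagittal_plan` objects.
#' @return list with elements `supine`, `standing` (both `spine_model`)
#'   and `gt_transforms` (named list of `rigid_transform`).
#' @export
make_pose_pair <- function(shapes, supine_plan, standing_plan) {
  supine <- assemble_spine(shapes, supine_plan)
  standing <- assemble_spine(shapes, standing_plan)
  gt <- lapply(vertebra_labels(), function(l)
    compose_transforms(standing$vertebrae[[l]]$pose,
                       invert_transform(supine$vertebrae[[l]]$pose)))
  names(gt) <- vertebra_labels()
  list(supine = supine, standing = standing, gt_transforms = gt)
}
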